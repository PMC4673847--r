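# Loss-of-function screen: LoF extraction, zygosity partition, cohort
# homozygote-absence filter, cross-dataset call-type consistency, MAF
# spectra, per-gene counts, per-Mb hotspot densities and the validation
# arithmetic.

#' Extract LoF records from annotated variants
#'
#' LoF = most-severe class in stop_gained / splice_donor / splice_acceptor /
#' frameshift; donor and acceptor collapse into the single `splice_site` LoF
#' class.  The zygosity partition over the sequenced samples is
#' `hom_all_samples` (no sample heterozygous; all carriers homozygous for
#' the variant allele) versus `het_in_ge1_sample`.
#'
#' @param annotation `per_variant` table from [annotate_variants()].
#' @param vset the [variant_set()] the annotation came from (for genotypes).
#' @param known_keys optional known-site keys for the novelty flag.
#' @return data.frame of LoF records (`lof_class`, `gene_id`, `novel`,
#'   `zygosity_partition`, plus the allele columns).
#' @export
extract_lof <- function(annotation, vset, known_keys = character()) {
  lof <- annotation[annotation$is_lof, , drop = FALSE]
  if (!nrow(lof)) return(cbind(lof, data.frame(lof_class = character(),
                                               zygosity_partition = character(),
                                               novel = logical())))
  if (anyNA(lof$gene_id)) {
    stop("LoF variant without a gene id at row ",
         which(is.na(lof$gene_id))[1])
  }
  lof$lof_class <- ifelse(lof$most_severe %in%
                            c("splice_donor", "splice_acceptor"),
                          "splice_site", lof$most_severe)
  # records with no called carrier have no zygosity partition; drop and log
  carrier <- vapply(lof$site, function(s) {
    g <- parse_genotypes(vset$gt[s, ])
    any(gt_class(g[, 1], g[, 2]) %in% c("het", "hom_alt"))
  }, logical(1))
  if (any(!carrier)) {
    message(sprintf("extract_lof: dropped %d LoF records with no called carrier",
                    sum(!carrier)))
    lof <- lof[carrier, , drop = FALSE]
  }
  zyg <- vapply(lof$site, function(s) site_zygosity_class(vset$gt[s, ]),
                character(1))
  lof$zygosity_partition <- ifelse(zyg == "heterozygous",
                                   "het_in_ge1_sample", "hom_all_samples")
  lof$novel <- !(lof$key %in% known_keys)
  lof
}

#' Per-gene LoF counts
#'
#' @param lof LoF table from [extract_lof()].
#' @return list with `per_gene` (named integer vector) and `n_multi_lof`
#'   (number of genes with more than one LoF variant).
#' @export
per_gene_counts <- function(lof) {
  if (!nrow(lof)) return(list(per_gene = integer(0), n_multi_lof = 0L))
  tab <- table(lof$gene_id)
  cnt <- stats::setNames(as.integer(tab), names(tab))
  list(per_gene = cnt, n_multi_lof = sum(cnt > 1L))
}

#' Cohort homozygote-absence filter
#'
#' Screens for candidate recessive lethals: a LoF variant is retained iff no
#' animal in the cohort is homozygous for the variant allele.  Records with
#' no cohort entry (matched on the normalized `chrom:pos:ref:alt` key) are
#' dropped and logged, since absence of homozygotes cannot be established
#' for them.  Missing cohort genotypes are ignored.
#'
#' @param lof LoF table from [extract_lof()] (must carry a `key` column).
#' @param cohort cohort counts from [read_cohort()].
#' @return the LoF table restricted to cohort-covered records, with cohort
#'   counts, `cohort_maf` and `passes_absence_filter` attached.  Retained
#'   records are those with `passes_absence_filter == TRUE`.
#' @export
absence_filter <- function(lof, cohort) {
  m <- match(lof$key, cohort$key)
  dropped <- sum(is.na(m))
  if (dropped) {
    message(sprintf("absence_filter: dropped %d LoF records without cohort genotypes",
                    dropped))
  }
  keep <- !is.na(m)
  out <- lof[keep, , drop = FALSE]
  cc <- cohort[m[keep], c("n_hom_ref", "n_het", "n_hom_alt", "n_missing")]
  rownames(cc) <- NULL
  out <- cbind(out, cc)
  out$cohort_maf <- maf(out$n_hom_ref, out$n_het, out$n_hom_alt)
  out$passes_absence_filter <- out$n_hom_alt == 0L
  out
}

#' Cross-dataset call-type consistency
#'
#' Matches records against a second call set on `(chrom, pos)`:
#' `consistent` when the other dataset has the same variant type and the
#' same normalized alleles; `inconsistent` when the position matches but
#' the representation differs (notably SNP-vs-indel type flips); `absent`
#' when the other dataset has no call at the position.
#'
#' @param records data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param other data.frame with `chrom`, `pos`, `ref`, `alt` (normalized).
#' @return character vector of `{"consistent","inconsistent","absent"}`,
#'   one per record.
#' @export
cross_dataset_consistency <- function(records, other) {
  ok <- paste(records$chrom, records$pos)
  tk <- paste(other$chrom, other$pos)
  m <- match(ok, tk)
  out <- rep("absent", nrow(records))
  hit <- !is.na(m)
  same <- hit & records$ref == other$ref[m] & records$alt == other$alt[m] &
    variant_type(records$ref, records$alt) ==
      variant_type(other$ref[m], other$alt[m])
  out[hit] <- "inconsistent"
  out[same] <- "consistent"
  out
}

#' Minor allele frequency from genotype counts
#'
#' `p = (2*n_hom_alt + n_het) / (2*(n_hom_ref + n_het + n_hom_alt))`;
#' `maf = min(p, 1 - p)`.  Complete-case: missing genotypes are ignored.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (vectorized).
#' @return MAF in `[0, 0.5]`; `NA` when no genotype was called.
#' @export
maf <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  p <- ifelse(n > 0, (2 * n_hom_alt + n_het) / (2 * n), NA_real_)
  pmin(p, 1 - p)
}

#' MAF spectrum per LoF class
#'
#' Fraction of records per LoF class with MAF strictly above the cutoff.
#'
#' @param lof LoF table with `lof_class` and `cohort_maf` columns.
#' @param cutoff MAF threshold (default 0.05; strict inequality).
#' @return data.frame `lof_class`, `n`, `fraction_above`; classes with no
#'   records are absent.
#' @export
maf_spectrum <- function(lof, cutoff = 0.05) {
  if (!nrow(lof)) {
    return(data.frame(lof_class = character(), n = integer(),
                      fraction_above = numeric()))
  }
  sp <- split(lof$cohort_maf, lof$lof_class)
  data.frame(lof_class = names(sp),
             n = vapply(sp, length, 1L),
             fraction_above = vapply(sp, function(x)
               mean(x > cutoff, na.rm = TRUE), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-Mb LoF density and hotspot windows
#'
#' Bins records into fixed windows and flags windows whose count exceeds
#' `mean + k_sd * sd` computed over the non-empty bins of the whole genome;
#' contiguous flagged bins are merged into regions.
#'
#' @param chrom,pos record coordinates.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param bin_bp window width (default 1 Mb).
#' @param k_sd outlier threshold in SD units (default 3).
#' @return list with `track` (per-bin counts, as [variant_density()], plus a
#'   `flagged` column) and `regions` (merged flagged windows).
#' @export
hotspot_density <- function(chrom, pos, chrom_lengths, bin_bp = 1e6,
                            k_sd = 3) {
  track <- variant_density(chrom, pos, chrom_lengths, bin_bp)
  nz <- track$count[track$count > 0]
  thr <- if (length(nz) >= 2L) mean(nz) + k_sd * stats::sd(nz) else Inf
  track$flagged <- track$count > thr
  regions <- do.call(rbind, lapply(split(track, track$chrom), function(tr) {
    tr <- tr[order(tr$bin_start), ]
    f <- tr$flagged
    if (!any(f)) return(NULL)
    r <- rle(f)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(chrom = tr$chrom[1],
               start = tr$bin_start[starts[keep]],
               end = tr$bin_end[ends[keep]],
               n_bins = r$lengths[keep],
               max_count = vapply(keep, function(k)
                 max(tr$count[starts[k]:ends[k]]), 1L),
               stringsAsFactors = FALSE)
  }))
  if (is.null(regions)) {
    regions <- data.frame(chrom = character(), start = integer(),
                          end = integer(), n_bins = integer(),
                          max_count = integer())
  }
  rownames(regions) <- NULL
  list(track = track, threshold = thr, regions = regions)
}

#' False-positive rate of a genotyping validation assay
#'
#' `100 * n_false_positive / (n_assayed - n_failed)`, rounded half-up to one
#' decimal — the arithmetic used when a subset of called variants is
#' re-genotyped with an independent assay and some assays fail.
#'
#' @param n_assayed number of variants assayed.
#' @param n_failed number of assays that produced no result.
#' @param n_false_positive number of assayed variants not confirmed.
#' @return FPR as a percentage.
#' @export
validation_fpr <- function(n_assayed, n_failed, n_false_positive) {
  stopifnot(n_failed <= n_assayed)
  denom <- n_assayed - n_failed
  if (denom <= 0L) stop("no informative assays (denominator is zero)")
  pct_of(n_false_positive, denom)
}
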
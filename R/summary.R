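# Cohort-level variant summary statistics: zygosity/novelty/allelicity
# partitions, Ts/Tv, per-bin densities, and the 3n indel-length enrichment
# test for coding indels.

TS_PAIRS <- c("A:G", "G:A", "C:T", "T:C")

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; transversions everything else.  Each ALT
#' allele of a multiallelic SNP site counts separately.
#'
#' @param ref,alt single-base allele vectors.
#' @return the Ts/Tv ratio, or `NA` when there are no transversions (rather
#'   than infinity).
#' @export
titv <- function(ref, alt) {
  keep <- nchar(ref) == 1L & nchar(alt) == 1L
  pair <- paste(ref[keep], alt[keep], sep = ":")
  ts <- sum(pair %in% TS_PAIRS)
  tv <- sum(!pair %in% TS_PAIRS)
  if (tv == 0L) return(NA_real_)
  ts / tv
}

#' Cohort summary table
#'
#' Counts and half-up one-decimal percentages for the standard partitions of
#' a multi-sample call set: SNPs vs indels, homozygous vs heterozygous sites,
#' novel vs known (exact normalized-key match against the known set),
#' biallelic vs triallelic SNP sites, deletions vs insertions, and Ts/Tv.
#' Percentages are of the total of the same variant type (SNP classes over
#' total SNPs, indel classes over total indels).
#'
#' @param vset a [variant_set()].
#' @param known_keys character vector of known-site keys
#'   (`chrom:pos:ref:alt`), e.g. from [read_known_sites()].
#' @param ref_seqs optional reference for allele normalization before novelty
#'   matching; when `NULL` alleles are assumed already normalized.
#' @return object of class `variant_summary`: a list with `counts` (named
#'   list) and `table` (data.frame `class`, `count`, `pct`).
#' @export
summarize_variants <- function(vset, known_keys = character(),
                               ref_seqs = NULL) {
  v <- vset$variants
  if (!nrow(v)) {
    counts <- list(total_snps = 0L, hom_snps = 0L, het_snps = 0L,
                   novel_snps = 0L, known_snps = 0L, biallelic_snps = 0L,
                   triallelic_snps = 0L, ts_tv = NA_real_, total_indels = 0L,
                   hom_indels = 0L, het_indels = 0L, novel_indels = 0L,
                   known_indels = 0L, deletions = 0L, insertions = 0L)
    return(structure(list(counts = counts,
                          table = summary_counts_to_table(counts)),
                     class = "variant_summary"))
  }
  # records whose genotype columns carry no variant allele (possible in
  # multi-sample call sets when every carrier genotype is missing or
  # reference) are not summarizable sites; drop them with a logged count
  has_carrier <- vapply(seq_len(nrow(v)), function(i) {
    g <- parse_genotypes(vset$gt[i, ])
    any(gt_class(g[, 1], g[, 2]) %in% c("het", "hom_alt"))
  }, logical(1))
  if (any(!has_carrier)) {
    message(sprintf("summarize_variants: dropped %d records with no called carrier",
                    sum(!has_carrier)))
    vset <- variant_set(v[has_carrier, , drop = FALSE],
                        vset$gt[has_carrier, , drop = FALSE])
    v <- vset$variants
  }
  stype <- site_variant_type(v$ref, v$alt)
  zyg <- vapply(seq_len(nrow(v)),
                function(i) site_zygosity_class(vset$gt[i, ]), character(1))
  alleles <- split_alleles(vset)
  if (!is.null(ref_seqs)) alleles <- normalize_alleles(alleles, ref_seqs)
  else alleles$key <- variant_key(alleles$chrom, alleles$pos,
                                  alleles$ref, alleles$alt)
  # a site is known iff every one of its ALT alleles is in the known set
  site_known <- tapply(alleles$key %in% known_keys, alleles$site, all)
  site_known <- as.logical(site_known[as.character(seq_len(nrow(v)))])
  n_alts <- lengths(strsplit(v$alt, ",", fixed = TRUE))
  snp <- stype == "SNP"; ind <- stype == "indel"
  snp_alleles <- alleles[variant_type(alleles$ref, alleles$alt) == "SNP", ]
  ind_alleles <- alleles[variant_type(alleles$ref, alleles$alt) == "indel", ]
  counts <- list(
    total_snps = sum(snp),
    hom_snps = sum(snp & zyg == "homozygous"),
    het_snps = sum(snp & zyg == "heterozygous"),
    novel_snps = sum(snp & !site_known),
    known_snps = sum(snp & site_known),
    biallelic_snps = sum(snp & n_alts == 1L),
    triallelic_snps = sum(snp & n_alts == 2L),
    ts_tv = titv(snp_alleles$ref, snp_alleles$alt),
    total_indels = sum(ind),
    hom_indels = sum(ind & zyg == "homozygous"),
    het_indels = sum(ind & zyg == "heterozygous"),
    novel_indels = sum(ind & !site_known),
    known_indels = sum(ind & site_known),
    deletions = sum(indel_length(ind_alleles$ref, ind_alleles$alt) < 0L),
    insertions = sum(indel_length(ind_alleles$ref, ind_alleles$alt) > 0L))
  structure(list(counts = counts, table = summary_counts_to_table(counts)),
            class = "variant_summary")
}

summary_counts_to_table <- function(counts) {
  snp_tot <- counts$total_snps; ind_tot <- counts$total_indels
  row <- function(class, count, total) {
    data.frame(class = class, count = count,
               pct = if (is.na(count)) NA_real_ else pct_of(count, total),
               stringsAsFactors = FALSE)
  }
  rbind(row("total_snps", snp_tot, snp_tot),
        row("hom_snps", counts$hom_snps, snp_tot),
        row("het_snps", counts$het_snps, snp_tot),
        row("novel_snps", counts$novel_snps, snp_tot),
        row("known_snps", counts$known_snps, snp_tot),
        row("biallelic_snps", counts$biallelic_snps, snp_tot),
        row("triallelic_snps", counts$triallelic_snps, snp_tot),
        data.frame(class = "ts_tv", count = NA_integer_,
                   pct = if (is.na(counts$ts_tv)) NA_real_ else
                     round_half_up(counts$ts_tv, 2), stringsAsFactors = FALSE),
        row("total_indels", ind_tot, ind_tot),
        row("hom_indels", counts$hom_indels, ind_tot),
        row("het_indels", counts$het_indels, ind_tot),
        row("novel_indels", counts$novel_indels, ind_tot),
        row("known_indels", counts$known_indels, ind_tot),
        row("deletions", counts$deletions, ind_tot),
        row("insertions", counts$insertions, ind_tot))
}

#' @method print variant_summary
#' @export
print.variant_summary <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Per-bin variant density track
#'
#' Bins each chromosome into fixed windows (`[k*bin+1, (k+1)*bin]`, last bin
#' truncated) and reports the count and the per-kb density in each bin.
#'
#' @param chrom,pos variant coordinates (vectors of equal length).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param bin_bp bin width in bp (default 1 Mb).
#' @return data.frame `chrom`, `bin_start`, `bin_end`, `count`,
#'   `density_per_kb`.
#' @export
variant_density <- function(chrom, pos, chrom_lengths, bin_bp = 1e6) {
  bin_bp <- as.integer(bin_bp)
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    p <- pos[chrom == ch]
    if (length(p) && any(p > len | p < 1L)) {
      stop("variant beyond chromosome length on ", ch)
    }
    nb <- max(1L, as.integer(ceiling(len / bin_bp)))
    cnt <- tabulate((p - 1L) %/% bin_bp + 1L, nbins = nb)
    data.frame(chrom = ch,
               bin_start = (seq_len(nb) - 1L) * bin_bp + 1L,
               bin_end = pmin(seq_len(nb) * bin_bp, len),
               count = cnt,
               density_per_kb = cnt / (bin_bp / 1000),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' 3n enrichment of coding-sequence indel lengths
#'
#' Purifying selection against frameshifts leaves CDS indels enriched for
#' lengths that are multiples of three.  Operationalized as a two-sided
#' exact binomial test of the 3n count among CDS indels against the 3n
#' proportion in a background indel set.
#'
#' @param cds_lengths signed lengths of CDS indels.
#' @param background_lengths signed lengths of the background set (e.g. all
#'   genome-wide indels).
#' @return list with `proportion_3n_cds`, `proportion_3n_background`, `k`,
#'   `n`, and `p_value`.
#' @export
three_n_enrichment <- function(cds_lengths, background_lengths) {
  if (!length(cds_lengths) || !length(background_lengths)) {
    stop("both indel sets must be nonempty")
  }
  k <- sum(abs(cds_lengths) %% 3L == 0L)
  n <- length(cds_lengths)
  p0 <- mean(abs(background_lengths) %% 3L == 0L)
  pv <- stats::binom.test(k, n, p = p0, alternative = "two.sided")$p.value
  list(proportion_3n_cds = k / n, proportion_3n_background = p0,
       k = k, n = n, p_value = pv)
}
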
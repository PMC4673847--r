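# Array-vs-sequencing genotype concordance: allele mapping between chip A/B
# calls and VCF ref/alt alleles, the discordance taxonomy (over-called,
# under-called, inconsistent, undetected), and the per-sample report.

#' Map chip A/B alleles onto VCF ref/alt alleles
#'
#' Tries a direct base match first, then the complement (opposite-strand
#' manifest).  Palindromic chip pairs (A/T, C/G) cannot be strand-resolved
#' and are flagged ambiguous.
#'
#' @param alleleA,alleleB single-base chip alleles.
#' @param ref,alts VCF REF allele and character vector of ALT alleles.
#' @return list with `status` (`"ok"`, `"ambiguous"`, `"unmatchable"`) and,
#'   when ok, `idxA`/`idxB`: allele indices (0 = ref).
#' @export
map_chip_alleles <- function(alleleA, alleleB, ref, alts) {
  if (alleleA == comp_base(alleleB)) {
    return(list(status = "ambiguous"))
  }
  alleles <- c(ref, alts)
  try_match <- function(a, b) {
    ia <- match(a, alleles) - 1L; ib <- match(b, alleles) - 1L
    if (!is.na(ia) && !is.na(ib)) list(idxA = ia, idxB = ib) else NULL
  }
  m <- try_match(alleleA, alleleB)
  if (is.null(m)) m <- try_match(comp_base(alleleA), comp_base(alleleB))
  if (is.null(m)) return(list(status = "unmatchable"))
  c(list(status = "ok"), m)
}

#' Classify one chip/sequencing genotype pair
#'
#' The discordance taxonomy: same alleles = `concordant`; chip homozygous
#' seen heterozygous in sequencing = `overcalled`; chip heterozygous seen
#' homozygous (either allele) = `undercalled`; both homozygous but for
#' different alleles = `inconsistent`; no sequencing call = `undetected`.
#' Chip homozygous-reference pairs are not comparable (sequencing lists
#' variant sites only) and are an error.
#'
#' @param chip integer pair of chip allele indices (0 = ref).
#' @param seq integer pair of sequencing allele indices, or `NA` when the
#'   site/sample has no sequencing call.
#' @return one of `"concordant"`, `"overcalled"`, `"undercalled"`,
#'   `"inconsistent"`, `"undetected"`.
#' @export
classify_pair <- function(chip, seq) {
  chip <- sort(as.integer(chip))
  if (chip[1] == chip[2] && chip[1] == 0L) {
    stop("chip homozygous-reference genotypes are not comparable")
  }
  if (length(seq) == 1L || anyNA(seq)) return("undetected")
  seq <- sort(as.integer(seq))
  if (all(chip == seq)) return("concordant")
  chip_hom <- chip[1] == chip[2]
  seq_hom <- seq[1] == seq[2]
  if (chip_hom && !seq_hom) return("overcalled")
  if (!chip_hom && seq_hom) return("undercalled")
  "inconsistent"
}

#' Join chip genotypes to sequencing calls for one sample
#'
#' Joins on `(chrom, pos)`, maps chip A/B alleles onto VCF alleles, and
#' attaches the discordance category of every comparable pair.  Ambiguous
#' (palindromic) and unmatchable chip sites are excluded from rate
#' computation and logged; chip homozygous-reference calls are skipped
#' (sequencing-derived call sets list variant sites only).  Chip sites with
#' no VCF record are resolved against the reference: a homozygous call for
#' the reference base is hom-ref (skipped), anything else is an undetected
#' variant call.
#'
#' @param chip chip table from [read_chip_genotypes()].
#' @param vset sequencing calls as a [variant_set()].
#' @param sample sample name (must be in `vset`).
#' @param ref_seqs named [Biostrings::DNAStringSet] used to resolve unmatched
#'   chip sites.
#' @param exclude_ambiguous drop palindromic chip sites (default `TRUE`).
#' @return data.frame of pairs with `chip_class` (`"hom_alt"`/`"het"`) and
#'   `category`.
#' @export
match_chip_to_sequencing <- function(chip, vset, sample, ref_seqs,
                                     exclude_ambiguous = TRUE) {
  if (!sample %in% vset$samples) stop("sample ", sample, " absent from VCF")
  v <- vset$variants
  vk <- paste(v$chrom, v$pos)
  ck <- paste(chip$chrom, chip$pos)
  hit <- match(ck, vk)
  gt <- parse_genotypes(vset$gt[, sample])
  chip_class <- character(nrow(chip))
  category <- character(nrow(chip))
  status <- character(nrow(chip))
  for (i in seq_len(nrow(chip))) {
    cg <- chip$genotype[i]
    if (is.na(cg) || cg == "missing") { status[i] <- "chip_missing"; next }
    j <- hit[i]
    if (is.na(j)) {
      # no VCF record; orient the chip call against the reference base
      rb <- as.character(Biostrings::subseq(ref_seqs[[chip$chrom[i]]],
                                            chip$pos[i], chip$pos[i]))
      aA <- chip$alleleA[i]; aB <- chip$alleleB[i]
      if (aA == comp_base(aB)) {
        status[i] <- if (exclude_ambiguous) "ambiguous" else "unmatchable"
        next
      }
      if (!rb %in% c(aA, aB)) { aA <- comp_base(aA); aB <- comp_base(aB) }
      if (!rb %in% c(aA, aB)) { status[i] <- "unmatchable"; next }
      pair <- switch(cg, AA = c(aA, aA), AB = c(aA, aB), BB = c(aB, aB))
      if (all(pair == rb)) { status[i] <- "chip_hom_ref"; next }
      chip_class[i] <- if (pair[1] != pair[2]) "het" else "hom_alt"
      category[i] <- "undetected"
      status[i] <- "pair"
      next
    }
    alts <- strsplit(v$alt[j], ",", fixed = TRUE)[[1]]
    m <- map_chip_alleles(chip$alleleA[i], chip$alleleB[i], v$ref[j], alts)
    if (m$status == "ambiguous" && exclude_ambiguous) {
      status[i] <- "ambiguous"; next
    }
    if (m$status != "ok") { status[i] <- "unmatchable"; next }
    cpair <- switch(cg,
                    AA = c(m$idxA, m$idxA),
                    AB = c(m$idxA, m$idxB),
                    BB = c(m$idxB, m$idxB))
    if (all(cpair == 0L)) { status[i] <- "chip_hom_ref"; next }
    chip_class[i] <- if (cpair[1] != cpair[2]) "het" else "hom_alt"
    spair <- gt[j, ]
    category[i] <- classify_pair(cpair, if (anyNA(spair)) NA else spair)
    status[i] <- "pair"
  }
  n_excluded <- sum(status %in% c("ambiguous", "unmatchable"))
  if (n_excluded) {
    message(sprintf("match_chip_to_sequencing: excluded %d ambiguous/unmatchable chip sites",
                    n_excluded))
  }
  keep <- status == "pair"
  data.frame(chrom = chip$chrom[keep], pos = chip$pos[keep],
             chip_class = chip_class[keep], category = category[keep],
             stringsAsFactors = FALSE)
}

#' Per-sample concordance report
#'
#' One row per chip genotype class (homozygous-alternative, heterozygous)
#' with the counts of each discordance category and the detection /
#' concordance / category rates, all over the number of comparable chip
#' calls in the class.  Raw rates are kept alongside the half-up one-decimal
#' display values.
#'
#' @inheritParams match_chip_to_sequencing
#' @param pairs optionally, a precomputed pair table from
#'   [match_chip_to_sequencing()] (then `chip`, `vset`, `sample`, `ref_seqs`
#'   are ignored).
#' @return data.frame of class `concordance_report`.
#' @export
concordance_report <- function(chip = NULL, vset = NULL, sample = NULL,
                               ref_seqs = NULL, pairs = NULL,
                               exclude_ambiguous = TRUE) {
  if (is.null(pairs)) {
    pairs <- match_chip_to_sequencing(chip, vset, sample, ref_seqs,
                                      exclude_ambiguous)
  }
  out <- lapply(c("hom_alt", "het"), function(cls) {
    p <- pairs[pairs$chip_class == cls, , drop = FALSE]
    n_chip <- nrow(p)
    cnt <- function(cat) sum(p$category == cat)
    n_und <- cnt("undetected")
    n_det <- n_chip - n_und
    d <- data.frame(sample = sample %||% NA_character_, chip_class = cls,
                    n_chip = n_chip, n_detected = n_det,
                    n_concordant = cnt("concordant"),
                    n_overcalled = cnt("overcalled"),
                    n_undercalled = cnt("undercalled"),
                    n_inconsistent = cnt("inconsistent"),
                    n_undetected = n_und, stringsAsFactors = FALSE)
    if (n_chip == 0L) {
      d$detection_rate <- d$concordance_rate <- d$overcall_rate <-
        d$undercall_rate <- d$inconsistent_rate <- NA_real_
      d$detection_pct <- d$concordance_pct <- d$overcall_pct <-
        d$undercall_pct <- d$inconsistent_pct <- NA_real_
      return(d)
    }
    d$detection_rate <- d$n_detected / n_chip
    d$concordance_rate <- d$n_concordant / n_chip
    d$overcall_rate <- d$n_overcalled / n_chip
    d$undercall_rate <- d$n_undercalled / n_chip
    d$inconsistent_rate <- d$n_inconsistent / n_chip
    d$detection_pct <- pct_of(d$n_detected, n_chip)
    d$concordance_pct <- pct_of(d$n_concordant, n_chip)
    d$overcall_pct <- pct_of(d$n_overcalled, n_chip)
    d$undercall_pct <- pct_of(d$n_undercalled, n_chip)
    d$inconsistent_pct <- pct_of(d$n_inconsistent, n_chip)
    d
  })
  structure(do.call(rbind, out),
            class = c("concordance_report", "data.frame"))
}
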
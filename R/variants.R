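# Variant-level primitives: genotype parsing, allele splitting, indel
# normalization, variant typing and site zygosity.

#' Construct a variant set
#'
#' A `variant_set` is the in-memory form of a multi-sample VCF: a site table
#' (one row per VCF record, multiallelic records kept as one row with a
#' comma-separated ALT) plus a genotype matrix of raw GT strings with one
#' column per sample.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param gt character matrix (`nrow(variants)` x samples) of GT strings such
#'   as `"0/1"`; missing calls are `"./."`.
#' @return object of class `variant_set`.
#' @export
variant_set <- function(variants, gt) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)))
  gt <- as.matrix(gt)
  if (nrow(variants) != nrow(gt)) {
    stop("genotype matrix and site table disagree on record count")
  }
  variants$pos <- as.integer(variants$pos)
  bad <- which(!is_upper_acgt(variants$ref) |
                 !grepl("^[ACGT]+(,[ACGT]+)*$", variants$alt) |
                 variants$pos < 1L)
  if (length(bad)) {
    stop(sprintf("malformed variant record %d (%s:%s %s>%s)", bad[1],
                 variants$chrom[bad[1]], variants$pos[bad[1]],
                 variants$ref[bad[1]], variants$alt[bad[1]]))
  }
  structure(list(variants = variants, gt = gt,
                 samples = colnames(gt)), class = "variant_set")
}

#' @method print variant_set
#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d sites, %d samples (%s)\n",
              nrow(x$variants), length(x$samples),
              paste(utils::head(x$samples, 4), collapse = ", ")))
  invisible(x)
}

#' Parse GT strings into allele-index pairs
#'
#' @param gt character vector of VCF GT strings (`"0/1"`, `"1|1"`, `"./."`).
#' @return integer matrix with two columns (sorted so the smaller index is
#'   first); both entries `NA` for missing calls.
#' @export
parse_genotypes <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  a <- suppressWarnings(vapply(parts, function(p) as.integer(p[1]), 1L))
  b <- suppressWarnings(vapply(parts, function(p) as.integer(p[min(2, length(p))]), 1L))
  m <- cbind(pmin(a, b), pmax(a, b))
  m[is.na(a) | is.na(b), ] <- NA_integer_
  m
}

# Genotype class of an allele-index pair.
gt_class <- function(a, b) {
  ifelse(is.na(a), "missing",
         ifelse(a != b, "het",
                ifelse(a == 0L, "hom_ref", "hom_alt")))
}

#' Split multiallelic sites into one row per ALT allele
#'
#' Sites are counted at the record level (a triallelic SNP is one site) but
#' annotated and normalized per allele; this produces the per-allele table.
#'
#' @param vset a [variant_set()].
#' @return data.frame with columns `site` (row index into the site table),
#'   `chrom`, `pos`, `id`, `ref`, `alt`, `allele` (1-based ALT index).
#' @export
split_alleles <- function(vset) {
  v <- vset$variants
  alts <- strsplit(v$alt, ",", fixed = TRUE)
  n <- lengths(alts)
  data.frame(site = rep(seq_len(nrow(v)), n),
             chrom = rep(v$chrom, n), pos = rep(v$pos, n),
             id = rep(v$id, n), ref = rep(v$ref, n),
             alt = unlist(alts), allele = unlist(lapply(n, seq_len)),
             stringsAsFactors = FALSE)
}

#' Classify a single-ALT variant as SNP, indel or MNP
#'
#' @param ref,alt allele strings (vectorized).
#' @return character vector in `{"SNP","indel","MNP"}`.
#' @export
variant_type <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == 1L & la == 1L, "SNP", ifelse(lr != la, "indel", "MNP"))
}

# Site-level type over all ALT alleles of a record.
site_variant_type <- function(ref, alt_field) {
  vapply(seq_along(ref), function(i) {
    tt <- variant_type(ref[i], strsplit(alt_field[i], ",", fixed = TRUE)[[1]])
    if (all(tt == "SNP")) "SNP" else if (any(tt == "indel")) "indel" else "MNP"
  }, character(1))
}

#' Signed indel length
#'
#' @param ref,alt allele strings of an indel (vectorized).
#' @return `nchar(alt) - nchar(ref)`: negative for deletions, positive for
#'   insertions.  Calling this on a non-indel is an error.
#' @export
indel_length <- function(ref, alt) {
  if (any(variant_type(ref, alt) != "indel")) {
    stop("indel_length() called on a non-indel allele")
  }
  nchar(alt) - nchar(ref)
}

#' Normalize an indel representation
#'
#' Right-trims then left-trims shared bases and left-aligns the allele pair
#' against the reference so that every representation of the same event in a
#' repeat context maps to one canonical `(pos, ref, alt)`.  SNPs are returned
#' unchanged.  This is the standard VCF left-alignment recursion: while the
#' alleles end with the same base, drop it (extending one base leftwards from
#' the reference when an allele would become empty); then trim a shared
#' leading base whenever both alleles retain at least two bases.
#'
#' @param chrom,pos,ref,alt a single-ALT variant.
#' @param ref_seqs named [Biostrings::DNAStringSet] of reference sequences.
#' @return list with elements `chrom`, `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(chrom, pos, ref, alt, ref_seqs) {
  stopifnot(length(ref) == 1L, length(alt) == 1L)
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    return(list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt))
  }
  seq <- ref_seqs[[chrom]]
  if (is.null(seq)) stop("chromosome ", chrom, " absent from reference")
  pos <- as.integer(pos)
  last1 <- function(x) substr(x, nchar(x), nchar(x))
  repeat {
    changed <- FALSE
    if (last1(ref) == last1(alt)) {
      if (nchar(ref) == 1L || nchar(alt) == 1L) {
        if (pos == 1L) {
          stop("normalization left an allele without an anchor base at ",
               chrom, ":", pos)
        }
        b <- as.character(Biostrings::subseq(seq, pos - 1L, pos - 1L))
        ref <- paste0(b, ref); alt <- paste0(b, alt); pos <- pos - 1L
      }
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      changed <- TRUE
    }
    if (nchar(ref) > 1L && nchar(alt) > 1L &&
        substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nchar(ref))
      alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  if (nchar(ref) == 0L || nchar(alt) == 0L) {
    stop("normalization produced an empty allele at ", chrom, ":", pos)
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

#' Normalize every allele of a per-allele table
#'
#' @param alleles data.frame as produced by [split_alleles()].
#' @param ref_seqs named [Biostrings::DNAStringSet].
#' @return the table with `pos`, `ref`, `alt` replaced by normalized values
#'   and a `key` column (`chrom:pos:ref:alt`).
#' @export
normalize_alleles <- function(alleles, ref_seqs) {
  needs <- nchar(alleles$ref) > 1L | nchar(alleles$alt) > 1L
  for (i in which(needs)) {
    n <- normalize_variant(alleles$chrom[i], alleles$pos[i],
                           alleles$ref[i], alleles$alt[i], ref_seqs)
    alleles$pos[i] <- n$pos; alleles$ref[i] <- n$ref; alleles$alt[i] <- n$alt
  }
  alleles$key <- variant_key(alleles$chrom, alleles$pos, alleles$ref, alleles$alt)
  alleles
}

#' Site zygosity over all samples
#'
#' A called site is `"heterozygous"` when at least one sample carries the
#' variant in the heterozygous state and `"homozygous"` when every carrier is
#' homozygous for an ALT allele.  Missing genotypes never contribute.
#'
#' @param gt_row character vector of GT strings, one per sample.
#' @return `"heterozygous"` or `"homozygous"`; a site with no carrier among
#'   the samples is an error (it should not be in the call set).
#' @export
site_zygosity_class <- function(gt_row) {
  g <- parse_genotypes(gt_row)
  cls <- gt_class(g[, 1], g[, 2])
  if (any(cls == "het")) return("heterozygous")
  if (any(cls == "hom_alt")) return("homozygous")
  stop("site has no carrier of the variant allele among the samples")
}
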
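# Transcript models: strand-aware exon/CDS structure, interval helpers and
# the cached per-transcript lookup tables used by the consequence caller.

#' Construct a transcript model
#'
#' Coordinates are 1-based fully closed genomic intervals, matching GFF3.
#' Exons must be sorted and non-overlapping and every CDS interval must lie
#' inside an exon.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param biotype one of `"protein_coding"`, `"miRNA"`, `"other_noncoding"`.
#' @param exons data.frame with `start`, `end` (genomic order).
#' @param cds data.frame with `start`, `end`; zero rows for non-coding
#'   transcripts.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, biotype,
                             exons, cds = NULL) {
  if (is.null(cds)) cds <- data.frame(start = integer(), end = integer())
  exons <- data.frame(start = as.integer(exons$start), end = as.integer(exons$end))
  cds <- data.frame(start = as.integer(cds$start), end = as.integer(cds$end))
  stopifnot(strand %in% c("+", "-"),
            biotype %in% c("protein_coding", "miRNA", "other_noncoding"),
            nrow(exons) >= 1L, all(exons$start <= exons$end))
  if (is.unsorted(exons$start) ||
      (nrow(exons) > 1L && any(exons$start[-1] <= exons$end[-nrow(exons)]))) {
    stop("exons of ", transcript_id, " must be sorted and non-overlapping")
  }
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
    if (!inside) stop("CDS interval outside exons in ", transcript_id)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, biotype = biotype,
                 exons = exons, cds = cds),
            class = "transcript_model")
}

#' @method print transcript_model
#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s, %s strand, %s): %d exons, %d CDS intervals\n",
              x$transcript_id, x$biotype, x$strand, x$chrom,
              nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

# genomic span (c(start, end)) of a transcript
tx_span <- function(tx) c(tx$exons$start[1], tx$exons$end[nrow(tx$exons)])

# introns as a data.frame of closed genomic intervals (0 rows if single-exon)
tx_introns <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = tx$exons$end[-n] + 1L, end = tx$exons$start[-1] - 1L)
}

in_intervals <- function(pos, iv) {
  if (!nrow(iv)) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= iv$start & p <= iv$end), logical(1))
}

overlaps_intervals <- function(start, end, iv) {
  if (!nrow(iv)) return(FALSE)
  any(start <= iv$end & end >= iv$start)
}

# Precompute everything the consequence caller needs for one transcript.
# `chrom_seq` is the plain character string of the chromosome sequence.
build_tx_cache <- function(tx, chrom_seq) {
  span <- tx_span(tx)
  introns <- tx_introns(tx)
  plus <- tx$strand == "+"
  donor <- acceptor <- data.frame(start = integer(), end = integer())
  sregion <- data.frame(start = integer(), end = integer())
  if (nrow(introns)) {
    # donor = first two intron bases in transcription direction,
    # acceptor = last two; splice region = intron bases 3-8 from either
    # junction plus exon bases 1-3 adjacent to a junction
    donor <- if (plus) data.frame(start = introns$start, end = introns$start + 1L)
             else data.frame(start = introns$end - 1L, end = introns$end)
    acceptor <- if (plus) data.frame(start = introns$end - 1L, end = introns$end)
                else data.frame(start = introns$start, end = introns$start + 1L)
    sregion <- rbind(
      data.frame(start = introns$start + 2L,
                 end = pmin(introns$start + 7L, introns$end)),
      data.frame(start = pmax(introns$end - 7L, introns$start),
                 end = introns$end - 2L),
      # exonic side, 1-3 bases from each junction
      data.frame(start = pmax(introns$start - 3L, span[1]),
                 end = introns$start - 1L),
      data.frame(start = introns$end + 1L,
                 end = pmin(introns$end + 3L, span[2])))
    sregion <- sregion[sregion$start <= sregion$end, , drop = FALSE]
  }
  cds_pos <- integer(0); cds_seq <- ""; cds_len <- 0L
  if (nrow(tx$cds)) {
    cds_pos <- unlist(mapply(seq.int, tx$cds$start, tx$cds$end,
                             SIMPLIFY = FALSE))
    cds_len <- length(cds_pos)
    bases <- substring(chrom_seq, cds_pos, cds_pos)
    cds_seq <- if (plus) paste(bases, collapse = "") else
      paste(rev(comp_base(bases)), collapse = "")
  }
  list(tx = tx, chrom = tx$chrom, strand = tx$strand, plus = plus,
       biotype = tx$biotype, span = span, introns = introns,
       donor = donor, acceptor = acceptor, sregion = sregion,
       exons = tx$exons, cds = tx$cds, cds_pos = cds_pos,
       cds_seq = cds_seq, cds_len = cds_len,
       cds_gmin = if (length(cds_pos)) min(cds_pos) else NA_integer_,
       cds_gmax = if (length(cds_pos)) max(cds_pos) else NA_integer_)
}

# 1-based coding coordinate of a genomic position inside the CDS
genomic_to_cds <- function(cache, gpos) {
  i <- match(gpos, cache$cds_pos)
  if (cache$plus) i else cache$cds_len - i + 1L
}
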
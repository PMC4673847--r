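# Functional consequence classification of variant alleles against
# transcript models: one class per (allele, transcript) from a fixed
# taxonomy, a most-severe class per allele, and the LoF flag.

#' Functional class taxonomy
#'
#' The full fixed enumeration of per-transcript functional classes.
#' @export
FUNCTIONAL_CLASSES <- c(
  "intergenic", "intronic", "upstream", "downstream", "utr3", "utr5",
  "splice_region", "splice_donor", "splice_acceptor", "initiator_codon",
  "stop_gained", "frameshift", "missense", "synonymous",
  "coding_sequence_indeterminate", "inframe_deletion", "inframe_insertion",
  "stop_lost", "stop_retained", "noncoding_exon", "mature_miRNA",
  "nc_transcript")

#' Severity ranking (most severe first)
#'
#' Total order used to pick the most severe class across transcripts.  Ties
#' in the biological convention (donor/acceptor, the two inframe classes,
#' stop_retained/synonymous, upstream/downstream) are broken by this fixed
#' listing so that `most_severe` is deterministic.
#' @export
SEVERITY_ORDER <- c(
  "stop_gained", "frameshift", "splice_donor", "splice_acceptor",
  "stop_lost", "initiator_codon", "missense", "inframe_deletion",
  "inframe_insertion", "coding_sequence_indeterminate", "splice_region",
  "stop_retained", "synonymous", "utr5", "utr3", "noncoding_exon",
  "mature_miRNA", "nc_transcript", "intronic", "upstream", "downstream",
  "intergenic")

LOF_CLASSES <- c("stop_gained", "splice_donor", "splice_acceptor", "frameshift")

# Affected reference footprint of a normalized single-ALT variant:
# `first` is the first affected reference base (the anchor-adjacent base for
# indels), `win` the closed interval used for window-overlap tests
# (insertions use their two flanking bases).
affected_range <- function(pos, ref, alt) {
  type <- variant_type(ref, alt)
  lr <- nchar(ref)
  if (type == "SNP" || type == "MNP") {
    list(type = type, first = pos, win = c(pos, pos + lr - 1L))
  } else if (nchar(alt) < lr) {       # deletion
    list(type = "deletion", first = pos + 1L, win = c(pos + 1L, pos + lr - 1L))
  } else {                            # insertion
    list(type = "insertion", first = pos + 1L, win = c(pos, pos + 1L))
  }
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# substitute `base` at coding coordinate `c` of the cached CDS sequence and
# report the consequence of the codon change
snp_codon_effect <- function(cache, cpos, alt_base_coding) {
  codon_i <- (cpos - 1L) %/% 3L + 1L
  off <- (cpos - 1L) %% 3L + 1L
  codon <- substr(cache$cds_seq, 3L * codon_i - 2L, 3L * codon_i)
  alt_codon <- codon
  substr(alt_codon, off, off) <- alt_base_coding
  if (codon_i == 1L) return("initiator_codon")
  aa_ref <- translate_codon(codon); aa_alt <- translate_codon(alt_codon)
  if (aa_ref == "*" && aa_alt == "*") "stop_retained"
  else if (aa_alt == "*") "stop_gained"
  else if (aa_ref == "*") "stop_lost"
  else if (aa_ref == aa_alt) "synonymous"
  else "missense"
}

#' Locate a variant relative to one transcript
#'
#' Region membership of the first affected reference base: coding exon, UTR
#' (strand-resolved), non-coding exon, intron, the 5 kb flanks, or outside.
#'
#' @param pos,ref,alt normalized single-ALT variant.
#' @param tx a [transcript_model()] (must be on the variant's chromosome).
#' @param flank_bp flank width defining upstream/downstream (default 5000).
#' @return one of `"exonic_cds"`, `"exonic_utr5"`, `"exonic_utr3"`,
#'   `"exonic_noncoding"`, `"intronic"`, `"upstream"`, `"downstream"`,
#'   `"outside"`.
#' @export
locate_variant <- function(pos, ref, alt, tx, flank_bp = 5000L) {
  span <- tx_span(tx)
  fa <- affected_range(pos, ref, alt)$first
  plus <- tx$strand == "+"
  if (fa >= span[1] && fa <= span[2]) {
    if (in_intervals(fa, tx$exons)) {
      if (!nrow(tx$cds)) return("exonic_noncoding")
      cds_pos_all <- unlist(mapply(seq.int, tx$cds$start, tx$cds$end,
                                   SIMPLIFY = FALSE))
      if (fa %in% cds_pos_all) return("exonic_cds")
      if (fa < min(tx$cds$start)) {
        return(if (plus) "exonic_utr5" else "exonic_utr3")
      }
      return(if (plus) "exonic_utr3" else "exonic_utr5")
    }
    return("intronic")
  }
  if (fa < span[1] && fa >= span[1] - flank_bp) {
    return(if (plus) "upstream" else "downstream")
  }
  if (fa > span[2] && fa <= span[2] + flank_bp) {
    return(if (plus) "downstream" else "upstream")
  }
  "outside"
}

#' Splice-site class of a variant against one transcript
#'
#' Donor = first two intron bases in transcription direction; acceptor = last
#' two; splice region = exon bases 1-3 adjacent to a junction or intron bases
#' 3-8 from either junction, excluding the donor/acceptor dinucleotides.
#'
#' @param pos,ref,alt normalized single-ALT variant.
#' @param tx a multi-exon [transcript_model()].
#' @return `"splice_donor"`, `"splice_acceptor"`, `"splice_region"` or
#'   `"none"`.
#' @export
splice_class <- function(pos, ref, alt, tx) {
  cache <- build_tx_cache(tx, strrep("N", tx_span(tx)[2]))
  win <- affected_range(pos, ref, alt)$win
  if (overlaps_intervals(win[1], win[2], cache$donor)) return("splice_donor")
  if (overlaps_intervals(win[1], win[2], cache$acceptor)) return("splice_acceptor")
  if (overlaps_intervals(win[1], win[2], cache$sregion)) return("splice_region")
  "none"
}

#' Coding consequence of a SNP
#'
#' Splices the CDS, reverse-complements on the minus strand, and translates
#' the affected codon with the standard genetic code.  The initiator codon
#' takes precedence for codon 1.
#'
#' @param pos,ref,alt a SNP inside the CDS.
#' @param tx a coding [transcript_model()].
#' @param ref_seqs named [Biostrings::DNAStringSet].
#' @return one of `"stop_gained"`, `"stop_lost"`, `"stop_retained"`,
#'   `"missense"`, `"synonymous"`, `"initiator_codon"`, or
#'   `"coding_sequence_indeterminate"` when the CDS length is not a multiple
#'   of three.
#' @export
coding_snp_effect <- function(pos, ref, alt, tx, ref_seqs) {
  cache <- build_tx_cache(tx, as.character(ref_seqs[[tx$chrom]]))
  classify_coding(cache, pos, ref, alt)
}

#' Coding consequence of an indel or MNP
#'
#' Length not divisible by three gives `frameshift`; divisible by three gives
#' `inframe_insertion`/`inframe_deletion` by sign; an equal-length (MNP)
#' substitution inside the CDS is classified by translation; an indel
#' spanning a CDS boundary is `coding_sequence_indeterminate`.
#'
#' @inheritParams coding_snp_effect
#' @return the coding class string.
#' @export
coding_indel_effect <- function(pos, ref, alt, tx, ref_seqs) {
  cache <- build_tx_cache(tx, as.character(ref_seqs[[tx$chrom]]))
  classify_coding(cache, pos, ref, alt)
}

# coding classification given a cache; assumes the variant touches the CDS
classify_coding <- function(cache, pos, ref, alt) {
  if (cache$cds_len %% 3L != 0L) return("coding_sequence_indeterminate")
  fr <- affected_range(pos, ref, alt)
  if (fr$type == "SNP") {
    cpos <- genomic_to_cds(cache, pos)
    if (is.na(cpos)) return("coding_sequence_indeterminate")
    alt_coding <- if (cache$plus) alt else comp_base(alt)
    return(snp_codon_effect(cache, cpos, alt_coding))
  }
  if (fr$type == "MNP") {
    gpos <- seq.int(fr$win[1], fr$win[2])
    cp <- genomic_to_cds(cache, gpos)
    if (anyNA(cp)) return("coding_sequence_indeterminate")
    # rewrite the affected coding bases and compare translations of the
    # touched codons
    cds_alt <- cache$cds_seq
    bases <- strsplit(alt, "")[[1]]
    if (!cache$plus) bases <- rev(comp_base(bases))
    for (k in seq_along(cp)) {
      i <- sort(cp)[k]
      substr(cds_alt, i, i) <- bases[k]
    }
    cod_idx <- unique((sort(cp) - 1L) %/% 3L + 1L)
    if (1L %in% cod_idx) return("initiator_codon")
    ref_aa <- vapply(cod_idx, function(i)
      translate_codon(substr(cache$cds_seq, 3L * i - 2L, 3L * i)), "")
    alt_aa <- vapply(cod_idx, function(i)
      translate_codon(substr(cds_alt, 3L * i - 2L, 3L * i)), "")
    if (any(alt_aa == "*" & ref_aa != "*")) return("stop_gained")
    if (any(ref_aa == "*" & alt_aa != "*")) return("stop_lost")
    return(if (all(ref_aa == alt_aa)) "synonymous" else "missense")
  }
  if (fr$type == "deletion") {
    gone <- seq.int(fr$win[1], fr$win[2])
    inside <- gone %in% cache$cds_pos
    if (!all(inside)) return("coding_sequence_indeterminate")
    len <- nchar(alt) - nchar(ref)
    return(if (abs(len) %% 3L != 0L) "frameshift" else "inframe_deletion")
  }
  # insertion: coding only when strictly inside the CDS (both flanks);
  # a flank half in and half out spans a CDS boundary
  flank_in <- c(pos, pos + 1L) %in% cache$cds_pos
  if (xor(flank_in[1], flank_in[2])) return("coding_sequence_indeterminate")
  len <- nchar(alt) - nchar(ref)
  if (abs(len) %% 3L != 0L) "frameshift" else "inframe_insertion"
}

# Class of one allele against one cached transcript, or NA when the variant
# lies outside the transcript's annotation reach (span +/- flank).
# Precedence: donor/acceptor > coding classes > splice_region > UTR >
# intronic > noncoding classes > upstream/downstream.
classify_tx <- function(cache, chrom, pos, ref, alt, flank_bp = 5000L) {
  if (chrom != cache$chrom) return(NA_character_)
  fr <- affected_range(pos, ref, alt)
  win <- fr$win
  if (overlaps_intervals(win[1], win[2], cache$donor)) return("splice_donor")
  if (overlaps_intervals(win[1], win[2], cache$acceptor)) return("splice_acceptor")
  if (cache$cds_len > 0L) {
    touches_cds <- switch(fr$type,
      insertion = any(c(pos, pos + 1L) %in% cache$cds_pos),
      any(seq.int(win[1], win[2]) %in% cache$cds_pos))
    if (touches_cds) return(classify_coding(cache, pos, ref, alt))
  }
  if (overlaps_intervals(win[1], win[2], cache$sregion)) return("splice_region")
  fa <- fr$first
  span <- cache$span
  if (fa >= span[1] && fa <= span[2]) {
    if (in_intervals(fa, cache$exons)) {
      if (cache$cds_len > 0L) {
        side_low <- fa < cache$cds_gmin
        if (cache$plus) return(if (side_low) "utr5" else "utr3")
        return(if (side_low) "utr3" else "utr5")
      }
      return(if (cache$biotype == "miRNA") "mature_miRNA" else "noncoding_exon")
    }
    return(if (cache$cds_len > 0L) "intronic" else "nc_transcript")
  }
  if (fa < span[1] && fa >= span[1] - flank_bp) {
    return(if (cache$plus) "upstream" else "downstream")
  }
  if (fa > span[2] && fa <= span[2] + flank_bp) {
    return(if (cache$plus) "downstream" else "upstream")
  }
  NA_character_
}

#' Build an annotation index over transcript models
#'
#' Precomputes per-transcript caches (splice windows, CDS coordinates and
#' spliced sequence) plus a chromosome-window lookup, so that repeated calls
#' to [annotate_variants()] are cheap.
#'
#' @param models list of [transcript_model()] objects.
#' @param ref_seqs named [Biostrings::DNAStringSet].
#' @param flank_bp upstream/downstream flank width in bp (default 5000).
#' @return an opaque index object.
#' @export
build_annotation_index <- function(models, ref_seqs, flank_bp = 5000L) {
  chrom_chars <- new.env(parent = emptyenv())
  getchrom <- function(ch) {
    if (is.null(chrom_chars[[ch]])) {
      if (!ch %in% names(ref_seqs)) stop("chromosome ", ch, " absent from reference")
      chrom_chars[[ch]] <- as.character(ref_seqs[[ch]])
    }
    chrom_chars[[ch]]
  }
  caches <- lapply(models, function(m) build_tx_cache(m, getchrom(m$chrom)))
  spans <- do.call(rbind, lapply(caches, function(c)
    data.frame(chrom = c$chrom, wstart = c$span[1] - flank_bp,
               wend = c$span[2] + flank_bp, stringsAsFactors = FALSE)))
  spans$idx <- seq_len(nrow(spans))
  list(caches = caches, spans = spans, flank_bp = flank_bp,
       chrom_chars = chrom_chars, getchrom = getchrom)
}

#' Annotate variant alleles with functional consequences
#'
#' Every allele is classified against each transcript within reach (span
#' plus 5 kb flank); per-transcript classes are composed with the precedence
#' donor/acceptor > coding > splice region > UTR > intronic > noncoding >
#' flanks, and a most-severe class per allele is chosen with
#' [SEVERITY_ORDER] (ties across transcripts broken by transcript id).
#' Alleles reaching no transcript are `intergenic`.  `is_lof` marks
#' most-severe classes in stop_gained / splice_donor / splice_acceptor /
#' frameshift.
#'
#' @param alleles normalized per-allele table ([normalize_alleles()]).
#' @param index result of [build_annotation_index()]; alternatively pass
#'   `models` and `ref_seqs`.
#' @param models,ref_seqs used to build an index when `index` is `NULL`.
#' @return list with `per_tx` (one row per allele x transcript call) and
#'   `per_variant` (one row per allele: `most_severe`, `transcript_id`,
#'   `gene_id`, `is_lof`).
#' @export
annotate_variants <- function(alleles, index = NULL, models = NULL,
                              ref_seqs = NULL) {
  if (is.null(index)) index <- build_annotation_index(models, ref_seqs)
  n <- nrow(alleles)
  sev_rank <- stats::setNames(seq_along(SEVERITY_ORDER), SEVERITY_ORDER)
  per_tx <- vector("list", n)
  ms_class <- ms_tx <- ms_gene <- character(n)
  for (i in seq_len(n)) {
    ch <- alleles$chrom[i]; p <- alleles$pos[i]
    ref <- alleles$ref[i]; alt <- alleles$alt[i]
    # reference agreement check
    chseq <- index$getchrom(ch)
    if (substr(chseq, p, p + nchar(ref) - 1L) != ref) {
      stop(sprintf("REF allele disagrees with reference at %s:%d (%s)",
                   ch, p, ref))
    }
    cand <- index$spans$idx[index$spans$chrom == ch &
                              index$spans$wstart <= p + nchar(ref) &
                              index$spans$wend >= p]
    calls <- character(0); txids <- character(0); genes <- character(0)
    bios <- character(0)
    for (j in cand) {
      cache <- index$caches[[j]]
      cl <- classify_tx(cache, ch, p, ref, alt, index$flank_bp)
      if (!is.na(cl)) {
        calls <- c(calls, cl)
        txids <- c(txids, cache$tx$transcript_id)
        genes <- c(genes, cache$tx$gene_id)
        bios <- c(bios, cache$biotype)
      }
    }
    if (!length(calls)) {
      per_tx[[i]] <- data.frame(allele_row = i, transcript_id = NA_character_,
                                gene_id = NA_character_, biotype = NA_character_,
                                functional_class = "intergenic",
                                stringsAsFactors = FALSE)
      ms_class[i] <- "intergenic"; ms_tx[i] <- NA_character_
      ms_gene[i] <- NA_character_
    } else {
      per_tx[[i]] <- data.frame(allele_row = i, transcript_id = txids,
                                gene_id = genes, biotype = bios,
                                functional_class = calls,
                                stringsAsFactors = FALSE)
      ranks <- sev_rank[calls]
      best <- which(ranks == min(ranks))
      best <- best[order(txids[best])][1]
      ms_class[i] <- calls[best]; ms_tx[i] <- txids[best]
      ms_gene[i] <- genes[best]
    }
  }
  per_variant <- cbind(alleles,
                       data.frame(most_severe = ms_class,
                                  transcript_id = ms_tx, gene_id = ms_gene,
                                  is_lof = ms_class %in% LOF_CLASSES,
                                  stringsAsFactors = FALSE))
  list(per_tx = do.call(rbind, per_tx), per_variant = per_variant)
}
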
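# Seeded synthetic-data generator: a toy multi-chromosome reference with
# protein-coding and non-coding gene models, truth variants of every
# functional class placed so that their class holds by construction, sample
# genotypes under Hardy-Weinberg proportions, sequencing-genotype errors at
# configured per-chip-class rates, a cohort genotype matrix with optional
# homozygote exclusion for designated "lethal" variants, a known-sites
# subset, a second call set with injected SNP/indel type flips, and a truth
# table backing every downstream assertion.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a small deep-sequenced cattle
#' cohort: four sequenced animals, a 288-animal reference cohort, chip error
#' rates of the order seen on high-density genotyping arrays, and known-site
#' fractions matching a mature variant database (95.5% of SNPs, 82.1% of
#' indels known).
#'
#' @param seed integer root seed; all child streams derive from it.
#' @param n_chroms,chrom_length_bp genome shape.
#' @param n_genes,fraction_noncoding_genes gene-model shape.
#' @param class_counts named integer vector: truth variants per functional
#'   class (see [default_class_counts()]).
#' @param n_mnp_missense equal-length codon substitutions (MNPs) labelled
#'   missense.
#' @param n_samples number of sequenced individuals.
#' @param af_shape,af_shape_frameshift Beta shape parameters of the variant
#'   allele-frequency distribution: a U-shaped spectrum by default (clipped
#'   to `[0.02, 0.98]`), with frameshifts drawn rarer (capped at 0.5) to
#'   mirror purifying selection; designated lethal variants are additionally
#'   capped at 0.2.
#' @param ts_fraction probability that a truth SNP is a transition, fixing
#'   the simulated genome-wide Ts/Tv ratio at
#'   `ts_fraction / (1 - ts_fraction)`.
#' @param chip_error_rates named vector `overcall`, `undercall`,
#'   `inconsistent`: per chip-class probabilities that a sequencing genotype
#'   departs from the (truth) chip genotype.
#' @param seq_missing_rates named vector `hom_ref`, `het`, `hom_alt`:
#'   probability of a missing sequencing genotype by true genotype class
#'   (heterozygotes are missed most often, driving the detection rate).
#' @param cohort_size,cohort_missing_rate,cohort_coverage reference cohort
#'   shape; `cohort_coverage` is the fraction of truth variants genotyped in
#'   the cohort at all.
#' @param lethal_fraction fraction of LoF truth variants whose cohort
#'   homozygote draws are redrawn as heterozygotes (zero variant-allele
#'   homozygotes by construction).
#' @param known_fraction named vector `SNP`, `indel`: fraction of truth
#'   variants present in the known-sites set.
#' @param other_coverage fraction of truth variants called at all in the
#'   second (cross-check) dataset.
#' @param flip_indel_fraction,flip_snp_fraction fraction of covered indels /
#'   SNPs represented as the discordant type in the second dataset.
#' @param intergenic_indel_fraction fraction of intergenic truth variants
#'   emitted as short indels with a single-base-dominated length spectrum
#'   (the genome-wide background for the 3n enrichment test).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2,
                       chrom_length_bp = 200000,
                       n_genes = 20,
                       fraction_noncoding_genes = 0.2,
                       class_counts = default_class_counts(),
                       n_mnp_missense = 3,
                       n_samples = 4,
                       af_shape = c(0.4, 0.4),
                       af_shape_frameshift = c(0.5, 6),
                       ts_fraction = 2.11 / 3.11,
                       chip_error_rates = c(overcall = 0.002,
                                            undercall = 0.003,
                                            inconsistent = 1e-4),
                       seq_missing_rates = c(hom_ref = 0.01, het = 0.04,
                                             hom_alt = 0.002),
                       cohort_size = 288,
                       cohort_missing_rate = 0.01,
                       cohort_coverage = 1.0,
                       lethal_fraction = 0.16,
                       known_fraction = c(SNP = 0.955, indel = 0.821),
                       other_coverage = 0.97,
                       flip_indel_fraction = 0.3,
                       flip_snp_fraction = 0.005,
                       intergenic_indel_fraction = 0.12) {
  cfg <- as.list(environment())
  probs <- c(fraction_noncoding_genes, chip_error_rates, seq_missing_rates,
             cohort_missing_rate, cohort_coverage, lethal_fraction,
             known_fraction, other_coverage, flip_indel_fraction,
             flip_snp_fraction)
  stopifnot(all(probs >= 0 & probs <= 1),
            chrom_length_bp > 0, n_chroms >= 1, n_samples >= 1,
            all(class_counts >= 0))
  unknown <- setdiff(names(class_counts), names(default_class_counts()))
  if (length(unknown)) stop("unknown class in class_counts: ",
                            paste(unknown, collapse = ", "))
  structure(cfg, class = "sim_config")
}

#' Default per-class truth variant counts
#'
#' A scaled-down emulation of a genome-wide functional spectrum: intergenic
#' and intronic variants dominate, coding classes are rare, and every class
#' of the taxonomy is represented.
#' @return named integer vector.
#' @export
default_class_counts <- function() {
  c(intergenic = 80, intronic = 120, upstream = 30, downstream = 30,
    utr3 = 20, utr5 = 10, splice_region = 15, splice_donor = 10,
    splice_acceptor = 10, initiator_codon = 4, stop_gained = 15,
    frameshift = 40, missense = 60, synonymous = 60,
    coding_sequence_indeterminate = 6, inframe_deletion = 10,
    inframe_insertion = 8, stop_lost = 4, stop_retained = 4,
    noncoding_exon = 12, mature_miRNA = 6, nc_transcript = 5)
}

# split `total` into `k` parts, each >= min_part
random_composition <- function(total, k, min_part) {
  stopifnot(total >= k * min_part)
  extra <- total - k * min_part
  cuts <- sort(sample.int(extra + 1L, k - 1L, replace = TRUE) - 1L)
  min_part + diff(c(0L, cuts, extra))
}

# ---- gene structure ---------------------------------------------------------

# Build one coding transcript at genomic offset `at` (transcript span starts
# there); CDS length is a multiple of 3, starts ATG, ends with a stop.
build_coding_gene <- function(gid, tid, chrom, at) {
  strand <- sample(c("+", "-"), 1)
  n_ex <- sample(2:4, 1)
  n_codons <- sample(60:120, 1)
  chunks <- random_composition(3L * n_codons, n_ex, 30L)
  utr5 <- sample(40:90, 1)
  utr3 <- sample(60:150, 1)
  exon_lens <- chunks
  exon_lens[1] <- utr5 + chunks[1]
  exon_lens[n_ex] <- chunks[n_ex] + utr3
  intron_lens <- sample(150:400, n_ex - 1, replace = TRUE)
  # transcription-local CDS window within each transcription-order exon
  cds_from <- c(utr5 + 1L, rep(1L, n_ex - 1L))
  cds_to <- exon_lens
  cds_to[1] <- utr5 + chunks[1]
  cds_to[n_ex] <- chunks[n_ex]
  # genomic order: reverse everything for the minus strand
  if (strand == "-") {
    exon_lens <- rev(exon_lens); intron_lens <- rev(intron_lens)
    cds_from <- rev(cds_from); cds_to <- rev(cds_to)
    flip <- TRUE
  } else flip <- FALSE
  starts <- at + c(0L, cumsum(exon_lens[-n_ex] + intron_lens))
  ends <- starts + exon_lens - 1L
  if (flip) {
    # transcription-local coordinate 1 sits at the genomic END of each exon
    cds_start_g <- ends - (cds_to - 1L)
    cds_end_g <- ends - (cds_from - 1L)
  } else {
    cds_start_g <- starts + cds_from - 1L
    cds_end_g <- starts + cds_to - 1L
  }
  transcript_model(tid, gid, chrom, strand, "protein_coding",
                   exons = data.frame(start = starts, end = ends),
                   cds = data.frame(start = cds_start_g, end = cds_end_g))
}

build_noncoding_gene <- function(gid, tid, chrom, at, biotype) {
  strand <- sample(c("+", "-"), 1)
  if (biotype == "miRNA") {
    len <- sample(70:100, 1)
    exons <- data.frame(start = at, end = at + len - 1L)
  } else {
    l1 <- sample(100:200, 1); l2 <- sample(100:200, 1)
    intron <- sample(120:300, 1)
    exons <- data.frame(start = c(at, at + l1 + intron),
                        end = c(at + l1 - 1L, at + l1 + intron + l2 - 1L))
  }
  transcript_model(tid, gid, chrom, strand, biotype, exons = exons)
}

# lay out genes with 12 kb spacing so that 5 kb flanks never overlap and
# intergenic gaps remain
generate_gene_models <- function(cfg) {
  n_nc <- round(cfg$fraction_noncoding_genes * cfg$n_genes)
  cc <- function(n) {
    v <- cfg$class_counts[n]
    sum(v[!is.na(v)])
  }
  need_mirna <- cc("mature_miRNA") > 0
  need_ncrna <- cc(c("noncoding_exon", "nc_transcript")) > 0
  # split the non-coding quota between the two biotypes, honouring which
  # classes are requested; an unhostable request surfaces later as a
  # placement error rather than silently growing the gene set
  n_mirna <- if (need_mirna && n_nc > 0L) {
    if (need_ncrna) max(1L, n_nc %/% 2L) else n_nc
  } else if (need_ncrna) 0L else n_nc %/% 2L
  n_mirna <- min(n_mirna, n_nc)
  n_other <- n_nc - n_mirna
  biotypes <- c(rep("protein_coding", cfg$n_genes - n_nc),
                rep("miRNA", n_mirna), rep("other_noncoding", n_other))
  biotypes <- sample(biotypes)
  chrom_of <- rep_len(paste0("chr", seq_len(cfg$n_chroms)), cfg$n_genes)
  cursor <- stats::setNames(rep(6000L, cfg$n_chroms),
                            paste0("chr", seq_len(cfg$n_chroms)))
  models <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    ch <- chrom_of[i]
    gid <- sprintf("gene%03d", i); tid <- sprintf("tx%03d", i)
    m <- if (biotypes[i] == "protein_coding") {
      build_coding_gene(gid, tid, ch, cursor[ch])
    } else {
      build_noncoding_gene(gid, tid, ch, cursor[ch], biotypes[i])
    }
    span <- tx_span(m)
    if (span[2] + 6000L > cfg$chrom_length_bp) {
      stop("chromosome ", ch, " too short for the requested gene count; ",
           "increase chrom_length_bp or reduce n_genes")
    }
    cursor[ch] <- span[2] + 12000L
    models[[i]] <- m
  }
  names(models) <- vapply(models, function(m) m$transcript_id, "")
  models
}

# write designed coding sequences (ATG ... stop, no internal stop) and
# canonical GT/AG splice dinucleotides into the genome character vectors
imprint_gene_sequences <- function(genome, models) {
  gc <- Biostrings::GENETIC_CODE
  sense_codons <- names(gc)[gc != "*" & !names(gc) %in% "ATG"]
  for (m in models) {
    introns <- tx_introns(m)
    for (k in seq_len(nrow(introns))) {
      s <- introns$start[k]; e <- introns$end[k]
      if (m$strand == "+") {
        genome[[m$chrom]][c(s, s + 1L)] <- c("G", "T")
        genome[[m$chrom]][c(e - 1L, e)] <- c("A", "G")
      } else {
        genome[[m$chrom]][c(e, e - 1L)] <- c("C", "A")
        genome[[m$chrom]][c(s + 1L, s)] <- c("T", "C")
      }
    }
    if (!nrow(m$cds)) next
    n_codons <- sum(m$cds$end - m$cds$start + 1L) %/% 3L
    coding <- c("ATG", sample(sense_codons, n_codons - 2L, replace = TRUE),
                sample(STOP_CODONS, 1L))
    bases <- strsplit(paste(coding, collapse = ""), "")[[1]]
    cds_pos <- unlist(mapply(seq.int, m$cds$start, m$cds$end,
                             SIMPLIFY = FALSE))
    if (m$strand == "-") bases <- rev(comp_base(bases))
    genome[[m$chrom]][cds_pos] <- bases
  }
  genome
}

# ---- truth variant placement ------------------------------------------------

# occupied-position bookkeeping (one logical mask per chromosome)
occ_new <- function(chrom_lengths) {
  e <- new.env(parent = emptyenv())
  for (ch in names(chrom_lengths)) e[[ch]] <- logical(chrom_lengths[[ch]])
  e
}
occ_free <- function(occ, chrom, from, to) !any(occ[[chrom]][from:to])
occ_take <- function(occ, chrom, from, to, buffer = 2L) {
  occ[[chrom]][max(1L, from - buffer):min(length(occ[[chrom]]), to + buffer)] <- TRUE
}

# alternate allele draw; transitions drawn at `ts_prob` so the simulated
# call set reproduces a genome-wide Ts/Tv ratio of ts_prob/(1 - ts_prob)
TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
random_alt <- function(ref_base, ts_prob = NA) {
  others <- setdiff(c("A", "C", "G", "T"), ref_base)
  if (is.na(ts_prob)) return(sample(others, 1L))
  ts <- TRANSITION_OF[[ref_base]]
  if (stats::runif(1) < ts_prob) ts else sample(setdiff(others, ts), 1L)
}

# per-transcript position pools for the positionally defined SNP classes
build_position_pools <- function(models, flank_bp = 5000L) {
  pools <- list()
  add <- function(class, chrom, pos, tx, gene) {
    if (!length(pos)) return()
    pools[[class]][[length(pools[[class]]) + 1L]] <<-
      data.frame(chrom = chrom, pos = as.integer(pos), tx = tx, gene = gene,
                 stringsAsFactors = FALSE)
  }
  for (m in models) {
    span <- tx_span(m); introns <- tx_introns(m)
    plus <- m$strand == "+"
    junctions <- c(introns$start - 1L, introns$end + 1L)  # exonic junction bases
    if (m$biotype == "protein_coding") {
      for (k in seq_len(nrow(introns))) {
        s <- introns$start[k]; e <- introns$end[k]
        if (e - s + 1L >= 19L) add("intronic", m$chrom, (s + 8L):(e - 8L),
                                   m$transcript_id, m$gene_id)
        add("splice_region", m$chrom, c((s + 2L):(s + 7L), (e - 7L):(e - 2L)),
            m$transcript_id, m$gene_id)
        dn <- if (plus) c(s, s + 1L) else c(e - 1L, e)
        ac <- if (plus) c(e - 1L, e) else c(s, s + 1L)
        add("splice_donor", m$chrom, dn, m$transcript_id, m$gene_id)
        add("splice_acceptor", m$chrom, ac, m$transcript_id, m$gene_id)
      }
      cds_pos <- unlist(mapply(seq.int, m$cds$start, m$cds$end,
                               SIMPLIFY = FALSE))
      exon_pos <- unlist(mapply(seq.int, m$exons$start, m$exons$end,
                                SIMPLIFY = FALSE))
      utr <- setdiff(exon_pos, cds_pos)
      utr <- utr[vapply(utr, function(p)
        all(abs(p - junctions) >= 4L), logical(1))]
      low <- utr[utr < min(cds_pos)]; high <- utr[utr > max(cds_pos)]
      add(if (plus) "utr5" else "utr3", m$chrom, low,
          m$transcript_id, m$gene_id)
      add(if (plus) "utr3" else "utr5", m$chrom, high,
          m$transcript_id, m$gene_id)
    } else {
      exon_pos <- unlist(mapply(seq.int, m$exons$start, m$exons$end,
                                SIMPLIFY = FALSE))
      safe <- exon_pos[vapply(exon_pos, function(p)
        !length(junctions) || all(abs(p - junctions) >= 4L), logical(1))]
      add(if (m$biotype == "miRNA") "mature_miRNA" else "noncoding_exon",
          m$chrom, safe, m$transcript_id, m$gene_id)
      for (k in seq_len(nrow(introns))) {
        s <- introns$start[k]; e <- introns$end[k]
        if (e - s + 1L >= 19L) add("nc_transcript", m$chrom, (s + 8L):(e - 8L),
                                   m$transcript_id, m$gene_id)
      }
    }
    up <- if (plus) (span[1] - 4500L):(span[1] - 500L) else
      (span[2] + 500L):(span[2] + 4500L)
    dn <- if (plus) (span[2] + 500L):(span[2] + 4500L) else
      (span[1] - 4500L):(span[1] - 500L)
    add("upstream", m$chrom, up, m$transcript_id, m$gene_id)
    add("downstream", m$chrom, dn, m$transcript_id, m$gene_id)
    # initiator codon: the three genomic bases of codon 1
    if (m$biotype == "protein_coding") {
      cds_pos <- unlist(mapply(seq.int, m$cds$start, m$cds$end,
                               SIMPLIFY = FALSE))
      cod1 <- if (plus) cds_pos[1:3] else cds_pos[(length(cds_pos) - 2L):length(cds_pos)]
      add("initiator_codon", m$chrom, cod1, m$transcript_id, m$gene_id)
    }
  }
  lapply(pools, function(p) do.call(rbind, p))
}

build_intergenic_pool <- function(models, chrom_lengths, flank_bp = 5000L) {
  out <- lapply(names(chrom_lengths), function(ch) {
    mask <- logical(chrom_lengths[[ch]])
    mask[seq_len(min(1000L, length(mask)))] <- TRUE
    mask[max(1L, length(mask) - 999L):length(mask)] <- TRUE
    for (m in models) {
      if (m$chrom != ch) next
      span <- tx_span(m)
      mask[max(1L, span[1] - flank_bp - 1L):
             min(length(mask), span[2] + flank_bp + 1L)] <- TRUE
    }
    data.frame(chrom = ch, pos = which(!mask), tx = NA_character_,
               gene = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ---- codon-level truth construction ----------------------------------------

# cache with coding bookkeeping for placement (independent of the annotator's
# classification path: effects are established by translating codons here)
placement_cache <- function(m, genome) {
  cds_pos <- unlist(mapply(seq.int, m$cds$start, m$cds$end, SIMPLIFY = FALSE))
  plus <- m$strand == "+"
  bases <- genome[[m$chrom]][cds_pos]
  cds_seq <- if (plus) paste(bases, collapse = "") else
    paste(rev(comp_base(bases)), collapse = "")
  list(m = m, plus = plus, cds_pos = cds_pos, len = length(cds_pos),
       cds_seq = cds_seq, n_codons = length(cds_pos) %/% 3L)
}

# genomic position of coding coordinate c
g_of_c <- function(pc, cc) {
  if (pc$plus) pc$cds_pos[cc] else pc$cds_pos[pc$len - cc + 1L]
}

codon_str <- function(pc, i) substr(pc$cds_seq, 3L * i - 2L, 3L * i)

# Enumerate single-base substitutions of codon i producing a codon whose
# translation satisfies `want(aa_ref, aa_alt)`; returns rows of
# (coding_pos, ref_coding, alt_coding).
codon_substitutions <- function(pc, i, want) {
  gcde <- Biostrings::GENETIC_CODE
  cod <- codon_str(pc, i)
  aa_ref <- unname(gcde[cod])
  out <- NULL
  for (off in 1:3) {
    rb <- substr(cod, off, off)
    for (b in setdiff(c("A", "C", "G", "T"), rb)) {
      alt_cod <- cod
      substr(alt_cod, off, off) <- b
      if (want(aa_ref, unname(gcde[alt_cod]))) {
        out <- rbind(out, data.frame(cpos = 3L * (i - 1L) + off,
                                     refb = rb, altb = b,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# place one codon-effect SNP of the requested kind; returns a truth row or
# NULL when no placement was found
place_codon_snp <- function(class, pcs, occ, genome, max_try = 400L,
                            ts_prob = NA) {
  want <- switch(class,
    stop_gained = function(r, a) r != "*" && a == "*",
    stop_lost = function(r, a) r == "*" && a != "*",
    stop_retained = function(r, a) r == "*" && a == "*",
    missense = function(r, a) r != "*" && a != "*" && r != a,
    synonymous = function(r, a) r != "*" && a != "*" && r == a)
  for (try in seq_len(max_try)) {
    pc <- pcs[[sample.int(length(pcs), 1L)]]
    i <- if (class %in% c("stop_lost", "stop_retained")) pc$n_codons else
      sample(2:(pc$n_codons - 1L), 1L)
    cand <- codon_substitutions(pc, i, want)
    if (is.null(cand)) next
    if (!is.na(ts_prob)) {
      is_ts <- TRANSITION_OF[cand$refb] == cand$altb
      use <- if (any(is_ts) && (all(is_ts) || stats::runif(1) < ts_prob)) {
        which(is_ts)
      } else which(!is_ts)
      cand <- cand[use, , drop = FALSE]
    }
    pick <- cand[sample.int(nrow(cand), 1L), ]
    gpos <- g_of_c(pc, pick$cpos)
    if (!occ_free(occ, pc$m$chrom, gpos, gpos)) next
    ref <- if (pc$plus) pick$refb else comp_base(pick$refb)
    alt <- if (pc$plus) pick$altb else comp_base(pick$altb)
    stopifnot(genome[[pc$m$chrom]][gpos] == ref)
    occ_take(occ, pc$m$chrom, gpos, gpos)
    return(data.frame(chrom = pc$m$chrom, pos = gpos, ref = ref, alt = alt,
                      class = class, tx = pc$m$transcript_id,
                      gene = pc$m$gene_id, stringsAsFactors = FALSE))
  }
  NULL
}

# place a CDS indel (frameshift / inframe) wholly inside one CDS interval,
# at least 3 bp from the interval edges even after left-alignment
place_cds_indel <- function(class, pcs, occ, genome, ref_seqs,
                            max_try = 400L) {
  sizes <- switch(class,
    frameshift = c(1L, 2L, 4L),
    inframe_deletion = c(3L, 6L),
    inframe_insertion = c(3L, 6L))
  insertion <- class == "inframe_insertion" ||
    (class == "frameshift" && stats::runif(1) < 0.4)
  for (try in seq_len(max_try)) {
    pc <- pcs[[sample.int(length(pcs), 1L)]]
    ivs <- pc$m$cds
    k <- sample.int(nrow(ivs), 1L)
    s <- ivs$start[k]; e <- ivs$end[k]
    if (e - s + 1L < 30L) next
    d <- sample(sizes, 1L)
    if (class == "frameshift") insertion <- stats::runif(1) < 0.4
    if (insertion) {
      p <- sample((s + 3L):(e - 4L), 1L)
      ref <- genome[[pc$m$chrom]][p]
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), d, TRUE),
                               collapse = ""))
    } else {
      p <- sample((s + 2L):(e - 3L - d), 1L)
      ref <- paste(genome[[pc$m$chrom]][p:(p + d)], collapse = "")
      alt <- genome[[pc$m$chrom]][p]
    }
    nv <- normalize_variant(pc$m$chrom, p, ref, alt, ref_seqs)
    win <- affected_range(nv$pos, nv$ref, nv$alt)$win
    if (win[1] < s + 3L || win[2] > e - 3L) next
    if (!occ_free(occ, pc$m$chrom, win[1] - 1L, win[2] + 1L)) next
    occ_take(occ, pc$m$chrom, win[1], win[2])
    return(data.frame(chrom = nv$chrom, pos = nv$pos, ref = nv$ref,
                      alt = nv$alt, class = class, tx = pc$m$transcript_id,
                      gene = pc$m$gene_id, stringsAsFactors = FALSE))
  }
  NULL
}

# deletion spanning a CDS/UTR boundary inside one exon (indeterminate
# effect by construction); `boundaries` rows are consumed without
# replacement
place_boundary_indel <- function(pcs, occ, genome, ref_seqs,
                                 used_tx, max_try = 200L) {
  for (try in seq_len(max_try)) {
    pc <- pcs[[sample.int(length(pcs), 1L)]]
    side <- sample(c("low", "high"), 1L)
    key <- paste(pc$m$transcript_id, side)
    if (key %in% used_tx$keys) next
    b <- if (side == "low") min(pc$cds_pos) else max(pc$cds_pos)
    # deletion affecting [b-3, b+2]: three bases each side of the boundary
    p <- b - 4L
    ref <- paste(genome[[pc$m$chrom]][p:(p + 6L)], collapse = "")
    alt <- genome[[pc$m$chrom]][p]
    nv <- try(normalize_variant(pc$m$chrom, p, ref, alt, ref_seqs),
              silent = TRUE)
    if (inherits(nv, "try-error")) next
    win <- affected_range(nv$pos, nv$ref, nv$alt)$win
    # still partially inside and partially outside the CDS, and clear of
    # splice windows (same-exon construction keeps introns away)
    inside <- seq.int(win[1], win[2]) %in% pc$cds_pos
    if (!any(inside) || all(inside)) next
    exon_ok <- any(win[1] >= pc$m$exons$start & win[2] <= pc$m$exons$end)
    if (!exon_ok) next
    if (!occ_free(occ, pc$m$chrom, win[1] - 1L, win[2] + 1L)) next
    occ_take(occ, pc$m$chrom, win[1], win[2])
    used_tx$keys <- c(used_tx$keys, key)
    return(data.frame(chrom = nv$chrom, pos = nv$pos, ref = nv$ref,
                      alt = nv$alt, class = "coding_sequence_indeterminate",
                      tx = pc$m$transcript_id, gene = pc$m$gene_id,
                      stringsAsFactors = FALSE))
  }
  NULL
}

# equal-length codon replacement (MNP) with a different amino acid; the
# replacement differs at the first and last coding base so the MNP is
# already in canonical form
place_mnp_missense <- function(pcs, occ, genome, max_try = 400L) {
  gcde <- Biostrings::GENETIC_CODE
  for (try in seq_len(max_try)) {
    pc <- pcs[[sample.int(length(pcs), 1L)]]
    i <- sample(2:(pc$n_codons - 1L), 1L)
    cpos <- (3L * (i - 1L) + 1L):(3L * i)
    gpos <- sort(vapply(cpos, function(c) g_of_c(pc, c), 1L))
    if (gpos[3] - gpos[1] != 2L) next  # codon must be genomically contiguous
    cod <- codon_str(pc, i)
    aa <- unname(gcde[cod])
    if (aa == "*") next
    cands <- names(gcde)[gcde != "*" & gcde != aa &
                           substr(names(gcde), 1, 1) != substr(cod, 1, 1) &
                           substr(names(gcde), 3, 3) != substr(cod, 3, 3)]
    if (!length(cands)) next
    new_cod <- sample(cands, 1L)
    if (!occ_free(occ, pc$m$chrom, gpos[1], gpos[3])) next
    ref <- paste(genome[[pc$m$chrom]][gpos[1]:gpos[3]], collapse = "")
    alt <- if (pc$plus) new_cod else revcomp(new_cod)
    occ_take(occ, pc$m$chrom, gpos[1], gpos[3])
    return(data.frame(chrom = pc$m$chrom, pos = gpos[1], ref = ref,
                      alt = alt, class = "missense",
                      tx = pc$m$transcript_id, gene = pc$m$gene_id,
                      stringsAsFactors = FALSE))
  }
  NULL
}

# ---- main generator ---------------------------------------------------------

SNP_POOL_CLASSES <- c("intergenic", "intronic", "upstream", "downstream",
                      "utr3", "utr5", "splice_region", "splice_donor",
                      "splice_acceptor", "initiator_codon", "noncoding_exon",
                      "mature_miRNA", "nc_transcript")
CODON_SNP_CLASSES <- c("stop_gained", "missense", "synonymous", "stop_lost",
                       "stop_retained")
CDS_INDEL_CLASSES <- c("frameshift", "inframe_deletion", "inframe_insertion")

place_truth_variants <- function(cfg, models, genome, ref_seqs,
                                 chrom_lengths) {
  occ <- occ_new(chrom_lengths)
  coding <- Filter(function(m) m$biotype == "protein_coding", models)
  pcs <- lapply(coding, placement_cache, genome = genome)
  rows <- list()
  want <- function(cl) {
    v <- cfg$class_counts[cl]
    if (length(v) != 1L || is.na(v)) 0L else as.integer(v)
  }
  # constrained classes first (codon effects, CDS indels, boundary indels)
  for (cl in CODON_SNP_CLASSES) {
    for (i in seq_len(want(cl))) {
      r <- place_codon_snp(cl, pcs, occ, genome, ts_prob = cfg$ts_fraction)
      if (is.null(r)) stop("could not place a ", cl, " truth variant")
      rows[[length(rows) + 1L]] <- r
    }
  }
  for (cl in CDS_INDEL_CLASSES) {
    for (i in seq_len(want(cl))) {
      r <- place_cds_indel(cl, pcs, occ, genome, ref_seqs)
      if (is.null(r)) stop("could not place a ", cl, " truth variant")
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (want("coding_sequence_indeterminate") > 0L) {
    used_tx <- new.env(); used_tx$keys <- character(0)
    for (i in seq_len(want("coding_sequence_indeterminate"))) {
      r <- place_boundary_indel(pcs, occ, genome, ref_seqs, used_tx)
      if (is.null(r)) stop("could not place a boundary-spanning indel")
      rows[[length(rows) + 1L]] <- r
    }
  }
  for (i in seq_len(cfg$n_mnp_missense)) {
    r <- place_mnp_missense(pcs, occ, genome)
    if (is.null(r)) stop("could not place an MNP missense truth variant")
    rows[[length(rows) + 1L]] <- r
  }
  # positionally defined SNP classes from precomputed pools
  pools <- build_position_pools(models)
  pools$intergenic <- build_intergenic_pool(models, chrom_lengths)
  for (cl in SNP_POOL_CLASSES) {
    n <- want(cl)
    if (n == 0L) next
    pool <- pools[[cl]]
    if (is.null(pool) || !nrow(pool)) {
      stop("gene models cannot host any ", cl, " truth variant")
    }
    free <- logical(nrow(pool))
    for (ch in unique(pool$chrom)) {
      sel <- pool$chrom == ch
      free[sel] <- !occ[[ch]][pool$pos[sel]]
    }
    pool <- pool[free, , drop = FALSE]
    if (nrow(pool) < n) stop("pool for class ", cl, " exhausted (",
                             nrow(pool), " < ", n, ")")
    pick <- pool[sample.int(nrow(pool), n), , drop = FALSE]
    ref <- vapply(seq_len(n), function(i)
      genome[[pick$chrom[i]]][pick$pos[i]], "")
    alt <- unname(vapply(ref, random_alt, "", ts_prob = cfg$ts_fraction))
    if (cl == "intergenic" && cfg$intergenic_indel_fraction > 0) {
      # a fraction of intergenic variants are short indels with a natural,
      # single-base-dominated length spectrum (the genome-wide background
      # against which coding-indel 3n enrichment is measured)
      as_indel <- which(stats::runif(n) < cfg$intergenic_indel_fraction)
      for (i in as_indel) {
        d <- sample(c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 4L, 6L), 1L)
        p <- pick$pos[i]; ch <- pick$chrom[i]
        if (stats::runif(1) < 0.5) {           # deletion of d bases
          if (p + d > length(genome[[ch]]) - 1000L) next
          ref[i] <- paste(genome[[ch]][p:(p + d)], collapse = "")
          alt[i] <- genome[[ch]][p]
        } else {                               # insertion of d bases
          ref[i] <- genome[[ch]][p]
          alt[i] <- paste0(ref[i], paste(sample(c("A", "C", "G", "T"), d,
                                                TRUE), collapse = ""))
        }
        nv <- normalize_variant(ch, p, ref[i], alt[i], ref_seqs)
        pick$pos[i] <- nv$pos; ref[i] <- nv$ref; alt[i] <- nv$alt
      }
    }
    for (ch in unique(pick$chrom)) {
      sel <- pick$chrom == ch
      idx <- outer(pick$pos[sel], -2:2, "+")
      idx <- idx[idx >= 1L & idx <= length(occ[[ch]])]
      occ[[ch]][idx] <- TRUE
    }
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = pick$chrom, pos = pick$pos, ref = ref, alt = alt,
                 class = cl, tx = pick$tx, gene = pick$gene,
                 stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  truth
}

gt_string <- function(g) {
  out <- c("0/0", "0/1", "1/1")[g + 1L]
  out[is.na(g)] <- "./."
  out
}

#' Generate a complete synthetic study
#'
#' Emits, under `out_dir`: `reference.fa`, `genes.gff3`, `variants.vcf`
#' (multi-sample sequencing calls), one `chip_<sample>.tsv` per sample,
#' `cohort.tsv` (genotype counts for the reference cohort), `known_sites.tsv`,
#' `other_calls.tsv` (the cross-check call set) and `truth.tsv`.  The same
#' seed yields byte-identical outputs.
#'
#' Construction guarantees: every requested functional class is placed at a
#' position that satisfies its positional definition (codon effects are
#' established by translation at generation time); CDS lengths are multiples
#' of three; sample genotypes are Hardy-Weinberg draws at a per-variant
#' allele frequency with at least one true carrier per site; the chip
#' carries the truth genotypes of every SNP site while the sequencing
#' genotypes are corrupted at the configured per-chip-class rates; cohort
#' counts are Hardy-Weinberg draws except that designated "lethal" LoF
#' variants have their variant-allele homozygotes redrawn as heterozygotes.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return list with `paths`, `truth` (the truth table), `models`,
#'   `ref_seqs`, `chrom_lengths`, `samples` and `config`.
#' @export
simulate_study <- function(config, out_dir) {
  cfg <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chrom_lengths <- stats::setNames(rep(as.integer(cfg$chrom_length_bp),
                                       cfg$n_chroms),
                                   paste0("chr", seq_len(cfg$n_chroms)))
  set.seed(derive_seed(cfg$seed, 1L))
  genome <- lapply(chrom_lengths, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  models <- generate_gene_models(cfg)
  genome <- imprint_gene_sequences(genome, models)
  ref_seqs <- Biostrings::DNAStringSet(vapply(genome, paste, character(1),
                                              collapse = ""))
  set.seed(derive_seed(cfg$seed, 2L))
  truth <- place_truth_variants(cfg, models, genome, ref_seqs, chrom_lengths)
  n <- nrow(truth)
  truth$vtype <- variant_type(truth$ref, truth$alt)
  truth$is_lof <- truth$class %in% LOF_CLASSES
  truth$lof_class <- ifelse(!truth$is_lof, NA_character_,
                            ifelse(truth$class %in%
                                     c("splice_donor", "splice_acceptor"),
                                   "splice_site", truth$class))

  # --- allele frequencies and sample genotypes (Hardy-Weinberg) ---
  set.seed(derive_seed(cfg$seed, 3L))
  truth$lethal <- truth$is_lof & stats::runif(n) < cfg$lethal_fraction
  shp <- matrix(rep(cfg$af_shape, each = n), nrow = n)
  fs <- truth$class == "frameshift"
  shp[fs, 1] <- cfg$af_shape_frameshift[1]
  shp[fs, 2] <- cfg$af_shape_frameshift[2]
  truth$af <- pmin(pmax(stats::rbeta(n, shp[, 1], shp[, 2]), 0.02), 0.98)
  # deleterious frameshifts never drift to high frequency, and designated
  # recessive lethals segregate at low frequency
  truth$af[fs] <- pmin(truth$af[fs], 0.5)
  truth$af[truth$lethal] <- pmin(truth$af[truth$lethal], 0.2)
  samples <- paste0("S", seq_len(cfg$n_samples))
  true_g <- matrix(stats::rbinom(n * cfg$n_samples, 2L, rep(truth$af,
                                                            cfg$n_samples)),
                   nrow = n)
  repeat {
    bad <- which(rowSums(true_g > 0L) == 0L)
    if (!length(bad)) break
    true_g[bad, ] <- stats::rbinom(length(bad) * cfg$n_samples, 2L,
                                   rep(truth$af[bad], cfg$n_samples))
  }

  # --- sequencing-genotype corruption (chip classes carry the rates) ---
  set.seed(derive_seed(cfg$seed, 4L))
  po <- cfg$chip_error_rates[["overcall"]]
  pu <- cfg$chip_error_rates[["undercall"]]
  pi_ <- cfg$chip_error_rates[["inconsistent"]]
  pm <- cfg$seq_missing_rates
  seq_g <- true_g
  cat_m <- matrix("na", nrow = n, ncol = cfg$n_samples)
  is_snp <- truth$vtype == "SNP"
  u <- matrix(stats::runif(n * cfg$n_samples), nrow = n)
  uu <- matrix(stats::runif(n * cfg$n_samples), nrow = n)
  for (j in seq_len(cfg$n_samples)) {
    g <- true_g[, j]; uj <- u[, j]
    hom_alt <- is_snp & g == 2L
    sel <- hom_alt & uj < po
    seq_g[sel, j] <- 1L; cat_m[sel, j] <- "overcalled"
    sel2 <- hom_alt & uj >= po & uj < po + pi_
    seq_g[sel2, j] <- 0L; cat_m[sel2, j] <- "inconsistent"
    sel3 <- hom_alt & uj >= po + pi_ & uj < po + pi_ + pm[["hom_alt"]]
    seq_g[sel3, j] <- NA_integer_; cat_m[sel3, j] <- "undetected"
    cat_m[hom_alt & !(sel | sel2 | sel3), j] <- "concordant"
    het <- is_snp & g == 1L
    sel <- het & uj < pu
    seq_g[sel, j] <- ifelse(uu[sel, j] < 0.5, 0L, 2L)
    cat_m[sel, j] <- "undercalled"
    sel2 <- het & uj >= pu & uj < pu + pm[["het"]]
    seq_g[sel2, j] <- NA_integer_; cat_m[sel2, j] <- "undetected"
    cat_m[het & !(sel | sel2), j] <- "concordant"
    hom_ref <- is_snp & g == 0L
    sel <- hom_ref & uj < pm[["hom_ref"]]
    seq_g[sel, j] <- NA_integer_
    cat_m[hom_ref, j] <- "hom_ref"
    # non-SNP sites: missingness only
    ns <- !is_snp
    miss_p <- pm[c("hom_ref", "het", "hom_alt")][g + 1L]
    sel <- ns & uj < miss_p
    seq_g[sel, j] <- NA_integer_
  }
  truth$has_seq_carrier <- rowSums(seq_g > 0L, na.rm = TRUE) > 0L

  # --- chip manifest and per-sample chip files ---
  set.seed(derive_seed(cfg$seed, 5L))
  truth$chip_ambiguous <- is_snp & truth$alt == comp_base(truth$ref)
  a_is_ref <- stats::runif(n) < 0.5
  flip <- stats::runif(n) < 0.3
  alleleA <- ifelse(a_is_ref, truth$ref, truth$alt)
  alleleB <- ifelse(a_is_ref, truth$alt, truth$ref)
  alleleA[flip] <- comp_base(alleleA[flip])
  alleleB[flip] <- comp_base(alleleB[flip])

  # --- cohort genotype counts ---
  set.seed(derive_seed(cfg$seed, 6L))
  truth$cohort_covered <- stats::runif(n) < cfg$cohort_coverage
  n_missing <- stats::rbinom(n, cfg$cohort_size, cfg$cohort_missing_rate)
  hw <- cbind((1 - truth$af)^2, 2 * truth$af * (1 - truth$af), truth$af^2)
  counts <- t(vapply(seq_len(n), function(i)
    stats::rmultinom(1, cfg$cohort_size - n_missing[i], hw[i, ])[, 1],
    integer(3)))
  # lethal variants: homozygote draws redrawn as heterozygotes
  counts[truth$lethal, 2] <- counts[truth$lethal, 2] + counts[truth$lethal, 3]
  counts[truth$lethal, 3] <- 0L
  truth$n_hom_ref <- counts[, 1]; truth$n_het <- counts[, 2]
  truth$n_hom_alt <- counts[, 3]; truth$n_missing <- n_missing

  # --- second call set with injected type flips ---
  set.seed(derive_seed(cfg$seed, 7L))
  covered <- stats::runif(n) < cfg$other_coverage
  uflip <- stats::runif(n)
  is_indel <- truth$vtype == "indel"
  flip_now <- covered & ((is_indel & uflip < cfg$flip_indel_fraction) |
                           (is_snp & uflip < cfg$flip_snp_fraction))
  truth$other_status <- ifelse(!covered, "absent",
                               ifelse(flip_now, "inconsistent", "consistent"))
  truth$other_ref <- ifelse(covered, truth$ref, NA_character_)
  truth$other_alt <- ifelse(covered, truth$alt, NA_character_)
  for (i in which(flip_now)) {
    base <- genome[[truth$chrom[i]]][truth$pos[i]]
    if (is_indel[i]) {       # represented as a SNP in the other dataset
      truth$other_ref[i] <- base
      truth$other_alt[i] <- random_alt(base)
    } else {                 # SNP represented as an insertion
      truth$other_ref[i] <- base
      truth$other_alt[i] <- paste0(base, random_alt(base))
    }
  }

  # --- known-sites subset ---
  set.seed(derive_seed(cfg$seed, 8L))
  kf <- ifelse(is_snp, cfg$known_fraction[["SNP"]],
               cfg$known_fraction[["indel"]])
  truth$known <- stats::runif(n) < kf
  truth$id <- ifelse(truth$known, sprintf("kv%06d", seq_len(n)), ".")

  # --- emit files ---
  paths <- list(
    reference = file.path(out_dir, "reference.fa"),
    gff = file.path(out_dir, "genes.gff3"),
    vcf = file.path(out_dir, "variants.vcf"),
    cohort = file.path(out_dir, "cohort.tsv"),
    known = file.path(out_dir, "known_sites.tsv"),
    other = file.path(out_dir, "other_calls.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  Biostrings::writeXStringSet(ref_seqs, paths$reference, width = 70L)
  write_gene_models(models, paths$gff)
  gt_chr <- matrix(gt_string(seq_g), nrow = n, dimnames = list(NULL, samples))
  vset <- variant_set(data.frame(chrom = truth$chrom, pos = truth$pos,
                                 id = truth$id, ref = truth$ref,
                                 alt = truth$alt, stringsAsFactors = FALSE),
                      gt_chr)
  write_vcf(vset, paths$vcf, contigs = chrom_lengths)
  chip_paths <- character(0)
  for (j in seq_along(samples)) {
    g <- true_g[is_snp, j]
    code <- ifelse(g == 1L, "AB",
                   ifelse((g == 2L) == a_is_ref[is_snp], "BB", "AA"))
    # hom genotype letter: AA when the called allele is alleleA
    hom_is_A <- (g == 2L & !a_is_ref[is_snp]) | (g == 0L & a_is_ref[is_snp])
    code[g != 1L] <- ifelse(hom_is_A[g != 1L], "AA", "BB")
    chip <- data.frame(chrom = truth$chrom[is_snp], pos = truth$pos[is_snp],
                       alleleA = alleleA[is_snp], alleleB = alleleB[is_snp],
                       genotype = code, stringsAsFactors = FALSE)
    p <- file.path(out_dir, sprintf("chip_%s.tsv", samples[j]))
    write_tsv(chip, p)
    chip_paths <- c(chip_paths, p)
  }
  names(chip_paths) <- samples
  paths$chip <- chip_paths
  cov <- truth$cohort_covered
  write_tsv(data.frame(chrom = truth$chrom[cov], pos = truth$pos[cov],
                       ref = truth$ref[cov], alt = truth$alt[cov],
                       n_hom_ref = truth$n_hom_ref[cov],
                       n_het = truth$n_het[cov],
                       n_hom_alt = truth$n_hom_alt[cov],
                       n_missing = truth$n_missing[cov]), paths$cohort)
  kn <- truth$known
  write_tsv(data.frame(chrom = truth$chrom[kn], pos = truth$pos[kn],
                       ref = truth$ref[kn], alt = truth$alt[kn],
                       id = truth$id[kn]), paths$known)
  oth <- truth$other_status != "absent"
  write_tsv(data.frame(chrom = truth$chrom[oth], pos = truth$pos[oth],
                       ref = truth$other_ref[oth],
                       alt = truth$other_alt[oth]), paths$other)
  for (j in seq_along(samples)) {
    truth[[paste0("true_g_", samples[j])]] <- true_g[, j]
    truth[[paste0("gt_", samples[j])]] <- gt_chr[, j]
    truth[[paste0("chip_cat_", samples[j])]] <- cat_m[, j]
  }
  write_tsv(truth, paths$truth)
  list(paths = paths, truth = truth, models = models, ref_seqs = ref_seqs,
       chrom_lengths = chrom_lengths, samples = samples, config = cfg)
}

#' Synthetic gene-to-term annotation map
#'
#' Random term annotations over a gene universe, with one designated term
#' enriched in a supplied study set (used to exercise the
#' over-representation test end to end).
#'
#' @param genes gene universe (character vector).
#' @param study_genes subset in which `enriched_term` is over-represented.
#' @param n_terms number of terms.
#' @param enriched_term id of the enriched term.
#' @param seed integer seed.
#' @return data.frame `gene_id`, `term_id`.
#' @export
generate_term_map <- function(genes, study_genes = character(0),
                              n_terms = 10, enriched_term = "T01",
                              seed = 1) {
  set.seed(derive_seed(seed, 9L))
  terms <- sprintf("T%02d", seq_len(n_terms))
  rows <- lapply(genes, function(g) {
    mine <- sample(setdiff(terms, enriched_term),
                   sample(1:3, 1), replace = FALSE)
    p_enr <- if (g %in% study_genes) 0.7 else 0.15
    if (stats::runif(1) < p_enr) mine <- c(mine, enriched_term)
    data.frame(gene_id = g, term_id = mine, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Deterministic worked-example fixture
#'
#' A small study (about 160 truth variants, one chromosome) whose
#' concordance report, summary table and LoF screen results are precomputed
#' here directly from the truth table (plain tabulations, independent of the
#' analysis modules), so that end-to-end pipeline output can be compared
#' against known values.
#'
#' @param out_dir output directory.
#' @return list with `sim` (as [simulate_study()]) and `expected`
#'   (precomputed aggregates).
#' @export
worked_example_fixture <- function(out_dir) {
  counts <- c(intergenic = 30, intronic = 30, upstream = 8, downstream = 8,
              utr3 = 6, utr5 = 4, splice_region = 6, splice_donor = 4,
              splice_acceptor = 4, initiator_codon = 2, stop_gained = 6,
              frameshift = 12, missense = 10, synonymous = 10,
              coding_sequence_indeterminate = 2, inframe_deletion = 4,
              inframe_insertion = 3, stop_lost = 2, stop_retained = 2,
              noncoding_exon = 4, mature_miRNA = 2, nc_transcript = 2)
  cfg <- sim_config(seed = 104729, n_chroms = 1, chrom_length_bp = 140000,
                    n_genes = 8, fraction_noncoding_genes = 0.25,
                    class_counts = counts, n_mnp_missense = 1)
  sim <- simulate_study(cfg, out_dir)
  tr <- sim$truth
  is_snp <- tr$vtype == "SNP"
  comparable <- is_snp & !tr$chip_ambiguous
  concord <- lapply(sim$samples, function(s) {
    cat <- tr[[paste0("chip_cat_", s)]]
    g <- tr[[paste0("true_g_", s)]]
    cls <- ifelse(g == 1L, "het", ifelse(g == 2L, "hom_alt", "hom_ref"))
    keep <- comparable & cls %in% c("het", "hom_alt")
    tab <- table(factor(cls[keep], c("hom_alt", "het")),
                 factor(cat[keep], c("concordant", "overcalled",
                                     "undercalled", "inconsistent",
                                     "undetected")))
    as.data.frame.matrix(tab)
  })
  names(concord) <- sim$samples
  gt_cols <- paste0("gt_", sim$samples)
  zyg <- apply(as.matrix(tr[, gt_cols]), 1L, function(row) {
    if (!any(row %in% c("0/1", "1/1"))) return("none")
    if (any(row == "0/1")) "heterozygous" else "homozygous"
  })
  called <- zyg != "none"
  pair <- paste(tr$ref, tr$alt, sep = ":")
  ts <- sum(is_snp & called & pair %in% TS_PAIRS)
  tv <- sum(is_snp & called & !pair %in% TS_PAIRS)
  lof_rec <- tr$is_lof & tr$has_seq_carrier
  expected <- list(
    summary = list(
      total_snps = sum(is_snp & called),
      het_snps = sum(is_snp & zyg == "heterozygous"),
      hom_snps = sum(is_snp & zyg == "homozygous"),
      novel_snps = sum(is_snp & called & !tr$known),
      total_indels = sum(tr$vtype == "indel" & called),
      novel_indels = sum(tr$vtype == "indel" & called & !tr$known),
      deletions = sum(tr$vtype == "indel" & called &
                        nchar(tr$alt) < nchar(tr$ref)),
      insertions = sum(tr$vtype == "indel" & called &
                         nchar(tr$alt) > nchar(tr$ref)),
      ts_tv = ts / tv),
    concordance = concord,
    lof = list(
      n_records = sum(lof_rec),
      by_class = table(tr$lof_class[lof_rec]),
      n_hom_all = sum(lof_rec & zyg == "homozygous"),
      n_het_ge1 = sum(lof_rec & zyg == "heterozygous"),
      retained_keys = variant_key(tr$chrom, tr$pos, tr$ref, tr$alt)[
        lof_rec & tr$cohort_covered & tr$n_hom_alt == 0L]))
  list(sim = sim, expected = expected)
}
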
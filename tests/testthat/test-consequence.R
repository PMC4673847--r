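# Consequence classification: region location, splice rules, codon effects,
# composition and severity, each checked against an independent oracle.

test_that("locate_variant matches brute-force interval membership", {
  tx <- toy_tx_plus()
  # independent per-position region map from raw interval arithmetic
  brute_region <- function(p) {
    exons <- tx$exons; cds <- tx$cds
    in_iv <- function(p, iv) any(p >= iv$start & p <= iv$end)
    if (in_iv(p, cds)) return("exonic_cds")
    if (in_iv(p, exons)) {
      return(if (p < min(cds$start)) "exonic_utr5" else "exonic_utr3")
    }
    if (p >= 6001 && p <= 7000) return("intronic")
    if (p >= 6001 - 5000 && p < 6001) return("upstream")
    if (p > 7000 && p <= 7000 + 5000) return("downstream")
    "outside"
  }
  set.seed(1)
  pos <- sample(500:12000, 500)
  got <- vapply(pos, function(p) locate_variant(p, "A", "G", tx), "")
  expect_identical(got, vapply(pos, brute_region, ""))
  # boundary: exactly 5 kb away is a flank, 5001 bp is outside
  expect_identical(locate_variant(6001 - 5000, "A", "G", tx), "upstream")
  expect_identical(locate_variant(6001 - 5001, "A", "G", tx), "outside")
  expect_identical(locate_variant(3001, "A", "G", tx), "upstream")
})

test_that("splice classification matches the junction-distance rule table on both strands", {
  for (tx in list(toy_tx_plus(), toy_tx_minus())) {
    introns <- data.frame(start = tx$exons$end[-3] + 1,
                          end = tx$exons$start[-1] - 1)
    # independent rule: distances measured from each junction
    brute <- function(p) {
      for (k in 1:2) {
        s <- introns$start[k]; e <- introns$end[k]
        d5 <- p - s + 1          # position within intron from genomic left
        d3 <- e - p + 1          # from genomic right
        donor <- if (tx$strand == "+") d5 %in% 1:2 else d3 %in% 1:2
        acceptor <- if (tx$strand == "+") d3 %in% 1:2 else d5 %in% 1:2
        if (p >= s && p <= e) {
          if (donor) return("splice_donor")
          if (acceptor) return("splice_acceptor")
          if (d5 %in% 3:8 || d3 %in% 3:8) return("splice_region")
        } else {
          # exonic side: 1-3 bases from the junction
          if ((p < s && s - p <= 3) || (p > e && p - e <= 3)) {
            return("splice_region")
          }
        }
      }
      "none"
    }
    for (k in 1:2) {
      for (p in (introns$start[k] - 10):(introns$start[k] + 10)) {
        expect_identical(splice_class(p, "A", "G", tx), brute(p),
                         label = sprintf("%s strand pos %d", tx$strand, p))
      }
      for (p in (introns$end[k] - 10):(introns$end[k] + 10)) {
        expect_identical(splice_class(p, "A", "G", tx), brute(p),
                         label = sprintf("%s strand pos %d", tx$strand, p))
      }
    }
  }
})

test_that("trivial codon effects: TGG->TGA is stop gained, GCT->GCC synonymous", {
  # single-exon 4-codon transcript built by hand: ATG TGG GCT TAA
  seqs <- Biostrings::DNAStringSet(c(chrX = paste0(strrep("A", 100),
                                                   "ATGTGGGCTTAA",
                                                   strrep("A", 100))))
  tx <- transcript_model("t", "g", "chrX", "+", "protein_coding",
                         exons = data.frame(start = 101, end = 112),
                         cds = data.frame(start = 101, end = 112))
  expect_identical(coding_snp_effect(106, "G", "A", tx, seqs), "stop_gained")
  # third base of GCT: GCT -> GCC is alanine either way
  expect_identical(coding_snp_effect(109, "T", "C", tx, seqs), "synonymous")
  expect_identical(coding_snp_effect(108, "C", "G", tx, seqs), "missense")
  expect_identical(coding_snp_effect(112, "A", "G", tx, seqs), "stop_retained")
  expect_identical(coding_snp_effect(102, "T", "C", tx, seqs), "initiator_codon")
})

test_that("every single-base substitution in a 30-codon CDS matches the translation oracle", {
  # 30-codon single-exon CDS on each strand; oracle translates the full
  # reference and alternate coding sequences with Biostrings and compares
  # proteins, knowing only the affected codon index from plain arithmetic
  gc <- Biostrings::GENETIC_CODE
  set.seed(5)
  sense <- names(gc)[gc != "*"]
  coding <- paste(c("ATG", sample(sense, 28, TRUE), "TGA"), collapse = "")
  for (strand in c("+", "-")) {
    flank1 <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
    flank2 <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
    genomic_cds <- if (strand == "+") coding else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(coding)))
    chrom <- paste0(flank1, genomic_cds, flank2)
    seqs <- Biostrings::DNAStringSet(c(chrS = chrom))
    tx <- transcript_model("t", "g", "chrS", strand, "protein_coding",
                           exons = data.frame(start = 81, end = 170),
                           cds = data.frame(start = 81, end = 170))
    translate_str <- function(s) {
      as.character(Biostrings::translate(Biostrings::DNAString(s),
                                         no.init.codon = TRUE))
    }
    p_ref <- translate_str(coding)
    n_checked <- 0L
    for (p in 81:170) {
      c_coord <- if (strand == "+") p - 80L else 170L - p + 1L
      ref_b <- substr(chrom, p, p)
      for (alt_b in setdiff(c("A", "C", "G", "T"), ref_b)) {
        coding_alt <- coding
        cb <- if (strand == "+") alt_b else chartr("ACGT", "TGCA", alt_b)
        substr(coding_alt, c_coord, c_coord) <- cb
        codon_i <- (c_coord - 1) %/% 3 + 1
        p_alt <- translate_str(coding_alt)
        ar <- substr(p_ref, codon_i, codon_i)
        aa <- substr(p_alt, codon_i, codon_i)
        expected <- if (codon_i == 1) "initiator_codon"
          else if (ar == "*" && aa == "*") "stop_retained"
          else if (aa == "*") "stop_gained"
          else if (ar == "*") "stop_lost"
          else if (ar == aa) "synonymous" else "missense"
        expect_identical(coding_snp_effect(p, ref_b, alt_b, tx, seqs),
                         expected,
                         label = sprintf("%s strand pos %d %s>%s",
                                         strand, p, ref_b, alt_b))
        n_checked <- n_checked + 1L
      }
    }
    expect_equal(n_checked, 270L)
  }
})

test_that("coding indel effects match the length/sign/boundary oracle", {
  seq_str <- toy_chrom_seq()
  tx <- toy_tx_plus()
  seq_str <- imprint_toy_cds(seq_str, tx)
  seqs <- toy_ref(seq_str)
  cds_pos <- unlist(mapply(seq.int, tx$cds$start, tx$cds$end, SIMPLIFY = FALSE))
  set.seed(21)
  n_checked <- 0L
  while (n_checked < 200L) {
    k <- sample(1:3, 1)
    s <- tx$cds$start[k]; e <- tx$cds$end[k]
    d <- sample(1:6, 1)
    if (runif(1) < 0.5) {   # deletion anchored at p, removing p+1 .. p+d
      p <- sample((s - 8):(e + 2), 1)
      if (p < 1) next
      ref <- substr(seq_str, p, p + d)
      alt <- substr(seq_str, p, p)
      affected <- (p + 1):(p + d)
      inside <- affected %in% cds_pos
      expected <- if (!any(inside)) NA_character_
        else if (!all(inside)) "coding_sequence_indeterminate"
        else if (d %% 3 != 0) "frameshift" else "inframe_deletion"
    } else {                # insertion between p and p+1
      p <- sample((s - 8):(e + 2), 1)
      if (p < 1) next
      ref <- substr(seq_str, p, p)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), d, TRUE),
                               collapse = ""))
      flank_in <- c(p, p + 1) %in% cds_pos
      expected <- if (!any(flank_in)) NA_character_
        else if (xor(flank_in[1], flank_in[2])) "coding_sequence_indeterminate"
        else if (d %% 3 != 0) "frameshift" else "inframe_insertion"
    }
    if (is.na(expected)) next   # not a coding indel; out of scope here
    # skip events whose footprint reaches a splice donor/acceptor: those
    # outrank coding classes and are exercised in the splice tests
    if (expected == "coding_sequence_indeterminate" && k < 3 &&
        max(p + d, p + 1) > e) next
    expect_identical(coding_indel_effect(p, ref, alt, tx, seqs), expected,
                     label = sprintf("pos %d %s>%s", p, ref, alt))
    n_checked <- n_checked + 1L
  }
})

test_that("a transcript whose CDS length is not a multiple of three is indeterminate", {
  seqs <- Biostrings::DNAStringSet(c(chrX = strrep("ACGT", 100)))
  tx <- transcript_model("t", "g", "chrX", "+", "protein_coding",
                         exons = data.frame(start = 101, end = 150),
                         cds = data.frame(start = 101, end = 140))  # 40 bp
  expect_identical(coding_snp_effect(110, substr(strrep("ACGT", 100), 110, 110),
                                     "T", tx, seqs),
                   "coding_sequence_indeterminate")
})

test_that("annotation composes classes with the documented precedence", {
  seq_str <- imprint_toy_cds(toy_chrom_seq(), toy_tx_plus())
  seqs <- Biostrings::DNAStringSet(c(chrT = seq_str,
                                     chrE = strrep("ACGT", 500)))
  mirna <- transcript_model("txR", "geneR", "chrT", "+", "miRNA",
                            exons = data.frame(start = 200, end = 280))
  models <- list(txP = toy_tx_plus(), txR = mirna)
  idx <- build_annotation_index(models, seqs)
  ann_at <- function(p, alt = NULL, chrom = "chrT") {
    ref <- substr(as.character(seqs[[chrom]]), p, p)
    if (is.null(alt)) alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    al <- data.frame(site = 1L, chrom = chrom, pos = p, id = ".",
                     ref = ref, alt = alt, allele = 1L,
                     key = "k", stringsAsFactors = FALSE)
    annotate_variants(al, index = idx)$per_variant$most_severe
  }
  expect_identical(ann_at(240), "mature_miRNA")
  expect_identical(ann_at(900, chrom = "chrE"), "intergenic") # empty chromosome
  expect_identical(ann_at(6101), "splice_donor")    # intron base 1
  expect_identical(ann_at(6105), "splice_region")   # intron base 5
  expect_identical(ann_at(6399), "splice_acceptor") # intron base -2
  expect_identical(ann_at(6020), "utr5")
  expect_identical(ann_at(6950), "utr3")
  expect_identical(ann_at(6250), "intronic")
  expect_identical(ann_at(4000), "upstream")
  expect_identical(ann_at(9000), "downstream")
})

test_that("annotation is symmetric under strand mirroring", {
  L <- 12000
  seq_str <- imprint_toy_cds(toy_chrom_seq(), toy_tx_plus())
  mirror_str <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq_str)))
  idx_p <- build_annotation_index(list(toy_tx_plus()), toy_ref(seq_str))
  idx_m <- build_annotation_index(list(toy_tx_minus()), toy_ref(mirror_str))
  set.seed(8)
  pos <- sample(1200:11800, 150)
  for (p in pos) {
    ref <- substr(seq_str, p, p)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[sample(3, 1)]
    al <- data.frame(site = 1L, chrom = "chrT", pos = p, id = ".", ref = ref,
                     alt = alt, allele = 1L, key = "k",
                     stringsAsFactors = FALSE)
    alm <- al
    alm$pos <- L - p + 1
    alm$ref <- chartr("ACGT", "TGCA", ref)
    alm$alt <- chartr("ACGT", "TGCA", alt)
    expect_identical(annotate_variants(al, index = idx_p)$per_variant$most_severe,
                     annotate_variants(alm, index = idx_m)$per_variant$most_severe,
                     label = sprintf("pos %d", p))
  }
})

test_that("severity ranking is total and most_severe is order-invariant", {
  expect_setequal(SEVERITY_ORDER, FUNCTIONAL_CLASSES)
  seq_str <- imprint_toy_cds(toy_chrom_seq(), toy_tx_plus())
  seqs <- toy_ref(seq_str)
  # an overlapping non-coding transcript spanning the coding gene
  nc <- transcript_model("txN", "geneN", "chrT", "+", "other_noncoding",
                         exons = data.frame(start = 5900, end = 7100))
  m1 <- list(txP = toy_tx_plus(), txN = nc)
  m2 <- rev(m1)
  al <- data.frame(site = 1L, chrom = "chrT", pos = 6050, id = ".",
                   ref = substr(seq_str, 6050, 6050),
                   alt = setdiff(c("A", "C", "G", "T"),
                                 substr(seq_str, 6050, 6050))[1],
                   allele = 1L, key = "k", stringsAsFactors = FALSE)
  a1 <- annotate_variants(al, models = m1, ref_seqs = seqs)$per_variant
  a2 <- annotate_variants(al, models = m2, ref_seqs = seqs)$per_variant
  expect_identical(a1$most_severe, a2$most_severe)
  expect_identical(a1$transcript_id, a2$transcript_id)
})

test_that("annotation rejects variants disagreeing with the reference", {
  seq_str <- imprint_toy_cds(toy_chrom_seq(), toy_tx_plus())
  seqs <- toy_ref(seq_str)
  ref <- substr(seq_str, 6050, 6050)
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  al <- data.frame(site = 1L, chrom = "chrT", pos = 6050, id = ".",
                   ref = wrong, alt = ref, allele = 1L, key = "k",
                   stringsAsFactors = FALSE)
  expect_error(annotate_variants(al, models = list(toy_tx_plus()),
                                 ref_seqs = seqs), "disagrees")
})
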
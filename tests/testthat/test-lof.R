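# LoF screen: extraction and zygosity partition, per-gene counts, the
# homozygote-absence filter, cross-dataset consistency, MAF, hotspots and
# the validation arithmetic.

fake_annotation <- function(classes, genes = NULL, n_samples = 2,
                            gts = NULL) {
  n <- length(classes)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  if (is.null(gts)) gts <- matrix("0/1", n, n_samples)
  ann <- data.frame(site = seq_len(n), chrom = "chr1",
                    pos = 100L + 10L * seq_len(n), id = ".",
                    ref = "A", alt = "G", allele = 1L,
                    key = variant_key("chr1", 100L + 10L * seq_len(n), "A", "G"),
                    most_severe = classes, transcript_id = paste0("t", seq_len(n)),
                    gene_id = genes,
                    is_lof = classes %in% c("stop_gained", "splice_donor",
                                            "splice_acceptor", "frameshift"),
                    stringsAsFactors = FALSE)
  vset <- variant_set(ann[, c("chrom", "pos", "id", "ref", "alt")],
                      matrix(gts, n, n_samples,
                             dimnames = list(NULL, paste0("S", seq_len(n_samples)))))
  list(ann = ann, vset = vset)
}

test_that("LoF extraction keeps the four LoF classes and partitions zygosity", {
  fx <- fake_annotation(c("stop_gained", "missense", "frameshift",
                          "splice_donor", "synonymous"))
  lof <- extract_lof(fx$ann, fx$vset)
  expect_equal(nrow(lof), 3L)
  expect_setequal(lof$lof_class, c("stop_gained", "frameshift", "splice_site"))
  # all samples hom-alt -> hom_all_samples
  fx2 <- fake_annotation(c("stop_gained", "frameshift"),
                         gts = rbind(c("1/1", "1/1"), c("0/1", "1/1")))
  lof2 <- extract_lof(fx2$ann, fx2$vset)
  expect_equal(lof2$zygosity_partition,
               c("hom_all_samples", "het_in_ge1_sample"))
  # the partition is exhaustive and exclusive
  expect_true(all(lof2$zygosity_partition %in%
                    c("hom_all_samples", "het_in_ge1_sample")))
})

test_that("per-gene counts and multi-LoF genes", {
  fx <- fake_annotation(rep("stop_gained", 3), genes = c("g1", "g1", "g2"))
  g <- per_gene_counts(extract_lof(fx$ann, fx$vset))
  expect_equal(g$per_gene[["g1"]], 2L)
  expect_equal(g$per_gene[["g2"]], 1L)
  expect_equal(g$n_multi_lof, 1L)
  empty <- per_gene_counts(data.frame(gene_id = character(0)))
  expect_equal(empty$n_multi_lof, 0L)
  expect_length(empty$per_gene, 0L)
})

test_that("absence filter retains only cohort-zero-homozygote variants and drops uncovered records", {
  fx <- fake_annotation(rep("frameshift", 3))
  lof <- extract_lof(fx$ann, fx$vset)
  cohort <- data.frame(chrom = "chr1", pos = c(110L, 120L),
                       ref = "A", alt = "G",
                       n_hom_ref = c(280L, 279L), n_het = c(8L, 8L),
                       n_hom_alt = c(0L, 1L), n_missing = c(0L, 0L),
                       stringsAsFactors = FALSE)
  cohort$key <- variant_key(cohort$chrom, cohort$pos, cohort$ref, cohort$alt)
  expect_message(out <- absence_filter(lof, cohort), "dropped 1")
  expect_equal(nrow(out), 2L)
  expect_equal(out$passes_absence_filter, c(TRUE, FALSE))
  # filtering is idempotent: refiltering the retained set changes nothing
  kept <- out[out$passes_absence_filter, ]
  again <- absence_filter(kept, cohort)
  expect_equal(again$key, kept$key)
  expect_true(all(again$passes_absence_filter))
})

test_that("cross-dataset consistency flags type flips symmetrically", {
  ours <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                     ref = c("CA", "A", "G"), alt = c("C", "G", "T"),
                     stringsAsFactors = FALSE)
  other <- data.frame(chrom = "chr1", pos = c(100L, 200L),
                      ref = c("A", "A"), alt = c("G", "G"),
                      stringsAsFactors = FALSE)
  got <- cross_dataset_consistency(ours, other)
  expect_equal(got, c("inconsistent", "consistent", "absent"))
  # symmetry of type-flip detection
  rev_got <- cross_dataset_consistency(other[1, ], ours[1, ])
  expect_equal(rev_got, "inconsistent")
  # injected flips on synthetic truth are recovered exactly
  sim <- default_sim()
  tr <- sim$truth
  oth <- utils::read.delim(sim$paths$other, stringsAsFactors = FALSE)
  got2 <- cross_dataset_consistency(tr, oth)
  expect_identical(got2, tr$other_status)
})

test_that("MAF from genotype counts is complete-case and capped at 0.5", {
  expect_equal(maf(7, 2, 1), 0.2)
  expect_equal(maf(0, 0, 10), 0.0)   # fixation edge case
  expect_true(is.na(maf(0, 0, 0)))
  set.seed(12)
  g <- stats::rbinom(1e4, 2, 0.1)
  est <- maf(sum(g == 0), sum(g == 1), sum(g == 2))
  expect_lt(abs(est - 0.1), 3 * sqrt(0.1 * 0.9 / (2 * 1e4)))
  expect_true(all(maf(c(5, 0), c(0, 3), c(5, 7)) <= 0.5))
})

test_that("MAF spectrum uses a strict cutoff", {
  lof <- data.frame(lof_class = "stop_gained",
                    cohort_maf = c(0.04, 0.05, 0.06))
  sp <- maf_spectrum(lof)
  expect_equal(sp$fraction_above, 1 / 3)
  lof0 <- data.frame(lof_class = "frameshift", cohort_maf = c(0, 0))
  expect_equal(maf_spectrum(lof0)$fraction_above, 0.0)
})

test_that("hotspot windows are flagged at mean + 3 SD and merged", {
  # one loaded bin among 100 one-record bins
  chrom <- rep("c1", 159)
  pos <- c(seq(5e5, by = 1e6, length.out = 100),          # 1 per bin
           rep(42.5e6, 60))                               # hotspot in bin 43
  h <- hotspot_density(chrom, pos, c(c1 = 1e8))
  expect_equal(nrow(h$regions), 1L)
  expect_equal(h$regions$n_bins, 1L)
  expect_equal(h$regions$start, 42e6 + 1)
  # contiguous 6 Mb hotspot merges into one region spanning it
  pos2 <- c(seq(5e5, by = 1e6, length.out = 100),
            rep(seq(57.5e6, 62.5e6, by = 1e6), each = 30))
  h2 <- hotspot_density(rep("c1", length(pos2)), pos2, c(c1 = 1e8))
  expect_equal(nrow(h2$regions), 1L)
  expect_equal(h2$regions$n_bins, 6L)
  expect_equal(h2$regions$start, 57e6 + 1)
  expect_equal(h2$regions$end, 63e6)
  # uniform records rarely flag anything at 3 SD (dense bins, so the
  # per-bin counts are approximately normal)
  set.seed(3)
  flags <- vapply(1:100, function(i) {
    p <- sample.int(3e7, 3000, replace = TRUE)
    nrow(hotspot_density(rep("c1", 3000), p, c(c1 = 3e7))$regions) > 0
  }, logical(1))
  expect_lt(mean(flags), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("validation assay FPR arithmetic", {
  expect_equal(validation_fpr(58, 2, 4), 7.1)
  expect_equal(validation_fpr(10, 0, 0), 0.0)
  expect_equal(validation_fpr(10, 9, 1), 100.0)
  expect_error(validation_fpr(5, 5, 0), "denominator")
})

test_that("absence filter equals the truth lethal set on a synthetic cohort", {
  for (seed in c(11, 12)) {
    sim <- simulate_study(sim_config(seed = seed),
                          file.path(tempdir(), paste0("lof-seed", seed)))
    vs <- read_vcf(sim$paths$vcf)
    al <- normalize_alleles(split_alleles(vs), sim$ref_seqs)
    ann <- annotate_variants(al, models = sim$models, ref_seqs = sim$ref_seqs)
    lof <- suppressMessages(extract_lof(ann$per_variant, vs))
    filt <- suppressMessages(absence_filter(lof, read_cohort(sim$paths$cohort)))
    got <- sort(filt$key[filt$passes_absence_filter])
    tr <- sim$truth
    want_rows <- tr$is_lof & tr$has_seq_carrier & tr$cohort_covered &
      tr$n_hom_alt == 0L
    want <- sort(variant_key(tr$chrom, tr$pos, tr$ref, tr$alt)[want_rows])
    expect_identical(got, want)
    # every designated lethal that is covered and carried is retained
    lethal_keys <- variant_key(tr$chrom, tr$pos, tr$ref, tr$alt)[
      tr$lethal & tr$has_seq_carrier & tr$cohort_covered]
    expect_true(all(lethal_keys %in% got))
  }
})
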
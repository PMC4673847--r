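# Domain types, readers/writers, normalization and site classification.

test_that("VCF reading maps fields directly and preserves multiallelics", {
  p <- mini_vcf(c("chr1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/1\t1/1",
                  "chr1\t200\trs1\tA\tG,T\t.\t.\t.\tGT\t1/2\t./."))
  vs <- read_vcf(p)
  expect_equal(vs$variants$pos, c(100L, 200L))
  expect_equal(vs$variants$ref, c("A", "A"))
  expect_equal(vs$variants$alt, c("G", "G,T"))
  expect_equal(unname(vs$gt[1, ]), c("0/1", "1/1"))
  expect_equal(unname(vs$gt[2, 2]), "./.")
  al <- split_alleles(vs)
  expect_equal(nrow(al), 3L)
  expect_equal(al$alt, c("G", "G", "T"))
})

test_that("VCF without genotype columns is rejected", {
  p <- write_lines_tmp(c("##fileformat=VCFv4.2",
                         "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                         "chr1\t1\t.\tA\tG\t.\t.\t."), ".vcf")
  expect_error(read_vcf(p), "genotype")
})

test_that("VCF write/read round-trip is record-identical", {
  sim <- default_sim()
  vs <- read_vcf(sim$paths$vcf)
  keep <- seq_len(50)
  sub <- variant_set(vs$variants[keep, ], vs$gt[keep, , drop = FALSE])
  p <- tempfile(fileext = ".vcf")
  write_vcf(sub, p, contigs = sim$chrom_lengths)
  back <- read_vcf(p)
  expect_equal(back$variants, sub$variants, ignore_attr = TRUE)
  expect_equal(unname(back$gt), unname(sub$gt))
  expect_equal(back$samples, sub$samples)
})

test_that("normalization trims shared bases and leaves SNPs unchanged", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "GGGGGGGGGCAAAAGGG"))
  n <- normalize_variant("chr1", 10, "CAA", "CA", ref)
  expect_equal(n[c("pos", "ref", "alt")], list(pos = 10L, ref = "CA", alt = "C"))
  n2 <- normalize_variant("chr1", 5, "A", "G", ref)
  expect_equal(n2[c("pos", "ref", "alt")], list(pos = 5L, ref = "A", alt = "G"))
})

# Oracle: enumerate every (pos, ref, alt) representation of the same edited
# sequence and require all of them to normalize to one canonical variant.
enumerate_representations <- function(ctx, altseq, max_len = 8L) {
  reps <- list()
  diff <- nchar(altseq) - nchar(ctx)
  for (s in seq_len(nchar(ctx))) {
    for (e in s:min(nchar(ctx), s + max_len)) {
      alt_end <- e + diff
      if (alt_end < s) next
      ref <- substr(ctx, s, e)
      alt <- substr(altseq, s, alt_end)
      if (nchar(alt) == 0L) next
      ok_prefix <- substr(ctx, 1, s - 1) == substr(altseq, 1, s - 1)
      ok_suffix <- substr(ctx, e + 1, nchar(ctx)) ==
        substr(altseq, alt_end + 1, nchar(altseq))
      if (ok_prefix && ok_suffix) {
        reps[[length(reps) + 1L]] <- list(pos = s, ref = ref, alt = alt)
      }
    }
  }
  reps
}

test_that("normalization is representation-invariant and idempotent in repeat contexts", {
  set.seed(99)
  for (i in 1:20) {
    # random context with an embedded homopolymer / dinucleotide repeat
    unit <- sample(c("A", "T", "AT", "CA"), 1)
    ctx <- paste0(paste(sample(c("A", "C", "G", "T"), 4, TRUE), collapse = ""),
                  strrep(unit, sample(3:5, 1)),
                  paste(sample(c("A", "C", "G", "T"), 4, TRUE), collapse = ""))
    # delete or insert one repeat unit somewhere inside the repeat tract
    del <- sample(c(TRUE, FALSE), 1)
    cut <- 5 + sample(seq_len(nchar(unit) * 2), 1)
    altseq <- if (del) {
      paste0(substr(ctx, 1, cut - 1), substr(ctx, cut + nchar(unit), nchar(ctx)))
    } else {
      paste0(substr(ctx, 1, cut - 1), unit, substr(ctx, cut, nchar(ctx)))
    }
    if (altseq == ctx) next
    ref_seqs <- Biostrings::DNAStringSet(c(ctx = ctx))
    reps <- enumerate_representations(ctx, altseq)
    norm <- lapply(reps, function(r) {
      tryCatch(normalize_variant("ctx", r$pos, r$ref, r$alt, ref_seqs),
               error = function(e) NULL)
    })
    norm <- Filter(Negate(is.null), norm)
    keys <- vapply(norm, function(n) paste(n$pos, n$ref, n$alt), "")
    expect_length(unique(keys), 1L)
    # idempotence
    n1 <- norm[[1]]
    n2 <- normalize_variant("ctx", n1$pos, n1$ref, n1$alt, ref_seqs)
    expect_equal(n2, n1)
  }
})

test_that("variant typing and signed indel lengths", {
  expect_equal(variant_type(c("A", "CA", "AT"), c("G", "C", "GC")),
               c("SNP", "indel", "MNP"))
  expect_equal(indel_length(c("CA", "C"), c("C", "CTT")), c(-1L, 2L))
  expect_error(indel_length("A", "G"), "non-indel")
})

test_that("site zygosity equals the exhaustive decision table for <= 3 samples", {
  states <- c("0/0", "0/1", "1/1", "./.")
  for (ns in 1:3) {
    grid <- do.call(expand.grid, c(rep(list(states), ns),
                                   stringsAsFactors = FALSE))
    for (i in seq_len(nrow(grid))) {
      row <- unlist(grid[i, ])
      # independent rule table
      expected <- if (any(row == "0/1")) "heterozygous"
                  else if (any(row == "1/1")) "homozygous"
                  else NA
      if (is.na(expected)) {
        expect_error(site_zygosity_class(row), "no carrier")
      } else {
        expect_identical(site_zygosity_class(row), expected)
      }
    }
  }
})

test_that("gene model reader resolves hierarchy and validates structure", {
  gff <- write_lines_tmp(c(
    "##gff-version 3",
    "chr1\tx\tgene\t100\t400\t.\t+\t.\tID=g1",
    "chr1\tx\tmRNA\t100\t400\t.\t+\t.\tID=t1;Parent=g1;biotype=protein_coding",
    "chr1\tx\texon\t100\t200\t.\t+\t.\tParent=t1",
    "chr1\tx\texon\t300\t400\t.\t+\t.\tParent=t1",
    "chr1\tx\tCDS\t120\t200\t.\t+\t0\tParent=t1",
    "chr1\tx\tCDS\t300\t390\t.\t+\t0\tParent=t1"), ".gff3")
  models <- read_gene_models(gff)
  expect_length(models, 1L)
  m <- models[["t1"]]
  expect_equal(nrow(m$exons), 2L)
  expect_equal(m$cds$start, c(120L, 300L))
  expect_equal(m$gene_id, "g1")

  bad <- write_lines_tmp(c(
    "##gff-version 3",
    "chr1\tx\tgene\t100\t400\t.\t+\t.\tID=g1",
    "chr1\tx\tmRNA\t100\t400\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tx\texon\t100\t200\t.\t+\t.\tParent=t1",
    "chr1\tx\tCDS\t150\t250\t.\t+\t0\tParent=t1"), ".gff3")
  expect_error(read_gene_models(bad), "CDS")
})

test_that("gene models round-trip through GFF3 write/read", {
  sim <- default_sim()
  back <- read_gene_models(sim$paths$gff)
  expect_setequal(names(back), names(sim$models))
  for (id in names(sim$models)) {
    expect_equal(back[[id]]$exons, sim$models[[id]]$exons, ignore_attr = TRUE)
    expect_equal(back[[id]]$cds, sim$models[[id]]$cds, ignore_attr = TRUE)
    expect_equal(back[[id]]$strand, sim$models[[id]]$strand)
    expect_equal(back[[id]]$biotype, sim$models[[id]]$biotype)
  }
})

test_that("chip reader applies the exclusion filter and rejects duplicates", {
  p <- write_lines_tmp(c("chrom\tpos\talleleA\talleleB\tgenotype",
                         "chr1\t10\tA\tG\tAB",
                         "chr1\t20\tC\tT\tAA",
                         "MT\t5\tA\tG\tBB",
                         "chr2\t10\tG\tT\tBB",
                         "chr1\t30\tA\tC\tAB"), ".tsv")
  expect_message(d <- read_chip_genotypes(p), "dropped 1")
  expect_equal(nrow(d), 4L)
  pdup <- write_lines_tmp(c("chrom\tpos\talleleA\talleleB\tgenotype",
                            "chr1\t10\tA\tG\tAB",
                            "chr1\t10\tC\tT\tAA"), ".tsv")
  expect_error(read_chip_genotypes(pdup), "duplicate")
})

test_that("cohort VCF collapses to genotype counts", {
  gts <- c(rep("0/0", 7), rep("0/1", 2), "./.")
  p <- mini_vcf(paste(c("chr1", "50", ".", "A", "T", ".", ".", ".", "GT", gts),
                      collapse = "\t"),
                samples = paste0("c", 1:10))
  d <- read_cohort(p)
  expect_equal(unlist(d[1, c("n_hom_ref", "n_het", "n_hom_alt", "n_missing")],
                      use.names = FALSE), c(7L, 2L, 0L, 1L))
})

test_that("known-sites membership equals the generator's known flags", {
  sim <- default_sim()
  ks <- read_known_sites(sim$paths$known)
  truth_keys <- variant_key(sim$truth$chrom, sim$truth$pos,
                            sim$truth$ref, sim$truth$alt)
  expect_identical(truth_keys %in% ks$key, sim$truth$known)
})
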
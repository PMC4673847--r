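# Shared fixtures: a cached default synthetic study, toy transcripts with a
# hand-built chromosome, and small writers for inline VCF/GFF text.

# One default study per session, generated on first use.
default_sim <- function() {
  if (is.null(getOption("lofscreen.test.sim"))) {
    dir <- file.path(tempdir(), "lofscreen-default-sim")
    sim <- simulate_study(sim_config(seed = 42), dir)
    options(lofscreen.test.sim = sim)
  }
  getOption("lofscreen.test.sim")
}

write_lines_tmp <- function(lines, ext) {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# A deterministic toy chromosome and a 3-exon coding transcript on it.
# Layout (1-based, chrom length 12000):
#   exon1 6001-6100 (UTR5 6001-6040, CDS 6041-6100)
#   intron1 6101-6400
#   exon2 6401-6520 (all CDS)
#   intron2 6521-6820
#   exon3 6821-7000 (CDS 6821-6880, UTR3 6881-7000)
# CDS length = 60 + 120 + 60 = 240 (80 codons).
toy_chrom_seq <- function(seed = 7) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), 12000, replace = TRUE), collapse = "")
}

toy_tx_plus <- function() {
  transcript_model("txP", "geneP", "chrT", "+", "protein_coding",
                   exons = data.frame(start = c(6001, 6401, 6821),
                                      end = c(6100, 6520, 7000)),
                   cds = data.frame(start = c(6041, 6401, 6821),
                                    end = c(6100, 6520, 6880)))
}

# Mirror image of toy_tx_plus on the reverse-complemented chromosome:
# position p maps to L - p + 1.
toy_tx_minus <- function(L = 12000) {
  mirror <- function(x) L - x + 1
  transcript_model("txM", "geneM", "chrT", "-", "protein_coding",
                   exons = data.frame(start = mirror(c(7000, 6520, 6100)),
                                      end = mirror(c(6821, 6401, 6001))),
                   cds = data.frame(start = mirror(c(6880, 6520, 6100)),
                                    end = mirror(c(6821, 6401, 6041))))
}

toy_ref <- function(seq_str) {
  Biostrings::DNAStringSet(c(chrT = seq_str))
}

# Ensure the toy CDS is a clean reading frame (ATG ... stop, no internal
# stop) by imprinting a designed coding sequence, mirroring what the
# generator does.  Returns the updated chromosome string.
imprint_toy_cds <- function(seq_str, tx, seed = 11) {
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  n_cod <- sum(tx$cds$end - tx$cds$start + 1) %/% 3
  coding <- c("ATG", sample(sense, n_cod - 2, replace = TRUE),
              sample(c("TAA", "TAG", "TGA"), 1))
  bases <- strsplit(paste(coding, collapse = ""), "")[[1]]
  cds_pos <- unlist(mapply(seq.int, tx$cds$start, tx$cds$end,
                           SIMPLIFY = FALSE))
  if (tx$strand == "-") bases <- rev(chartr("ACGT", "TGCA", bases))
  ch <- strsplit(seq_str, "")[[1]]
  ch[cds_pos] <- bases
  paste(ch, collapse = "")
}

mini_vcf <- function(records, samples = c("S1", "S2")) {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), ".vcf")
}
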
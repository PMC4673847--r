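Package: lofscreen
Title: Variant Annotation, Genotype Concordance and Loss-of-Function
    Screening for Resequencing Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-variant-calling analysis toolkit for deep resequencing
    studies in livestock: functional consequence annotation of SNPs and
    indels against GFF3 gene models, cohort summary statistics
    (zygosity, novelty, Ts/Tv, indel length spectra and 3n enrichment),
    array-versus-sequencing genotype concordance with an explicit
    discordance taxonomy, loss-of-function (LoF) variant extraction with
    a cohort homozygote-absence filter for candidate recessive lethals,
    cross-dataset call-type consistency, minor allele frequency spectra,
    per-megabase density hotspot detection, and Fisher exact gene-set
    over/under-representation.  Includes a seeded synthetic-data
    generator that emits a toy reference genome, gene models and
    variant/genotype files with a complete truth table, used throughout
    the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    vcfR,
    yaml,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
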
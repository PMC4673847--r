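#!/usr/bin/env Rscript
# Step 1: generate the synthetic study.
#
# Emits a toy two-chromosome reference, 20 gene models, ~560 truth variants
# covering every functional class, genotypes for 4 sequenced samples, chip
# calls, a 288-animal cohort genotype table, a known-sites subset, a second
# call set with injected SNP/indel type flips, and the truth table.  Also
# writes a synthetic gene-to-term annotation map for the enrichment step.

suppressMessages(library(lofscreen))

seed <- as.integer(Sys.getenv("LOFSCREEN_SEED", "1"))
out <- "results/sim"
sim <- simulate_study(sim_config(seed = seed), out)

genes <- unique(vapply(sim$models, function(m) m$gene_id, ""))
lof_genes <- unique(sim$truth$gene[sim$truth$is_lof])
map <- generate_term_map(genes, lof_genes, seed = seed)
utils::write.table(map, file.path(out, "term_map.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d truth variants (%d LoF) over %d genes; outputs in %s\n",
            nrow(sim$truth), sum(sim$truth$is_lof), length(genes), out))
cat(sprintf("designated lethal variants (no cohort homozygote by construction): %d\n",
            sum(sim$truth$lethal)))
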
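#!/usr/bin/env Rscript
# Step 6: term over/under-representation of LoF-affected genes against the
# gene universe, two-sided Fisher exact with Bonferroni correction.

suppressMessages(library(lofscreen))

lof <- utils::read.delim("results/tables/lof_records.tsv")
map <- read_term_map("results/sim/term_map.tsv")

res <- test_term_enrichment(unique(lof$gene_id), map)
utils::write.table(res, "results/tables/enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

sig <- res[res$p_bonferroni < 0.05, ]
cat(sprintf("tested %d terms over %d study genes (universe %d); %d significant after Bonferroni\n",
            nrow(res), res$n_study[1], res$n_background[1], nrow(sig)))
print(utils::head(res[, c("term_id", "n_study_with_term",
                          "n_background_with_term", "direction",
                          "p_raw", "p_bonferroni")], 5), row.names = FALSE)
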
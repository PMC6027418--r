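#!/usr/bin/env Rscript
# Stage 4: gene-set over-representation of the candidates.
#
# Tests the stage-3 candidates against the supplied gene-set collection
# with the hypergeometric upper tail (universe: all genes that survived
# the expression floor, i.e. everything compared in stage 3), adjusting
# across sets with Benjamini-Hochberg.

suppressPackageStartupMessages(library(graftDE))

cm <- read_count_matrix("results/data/counts.tsv",
                        "results/data/gene_lengths.tsv",
                        "results/data/groups.tsv")
run <- consensus_de_pipeline(cm)
sets <- read_gmt("results/data/gene_sets.gmt")

res <- enrich(run$candidates$gene, sets, attr(run$pairwise, "genes"))
write.table(res, "results/enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("over-representation of the candidate genes:\n")
print(res[, c("set", "set_size", "overlap", "p_value", "adjusted_p")],
      row.names = FALSE)
cat(sprintf("top-ranked set: %s (p = %.3g)\n", res$set[1], res$p_value[1]))
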
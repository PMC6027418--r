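#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the study design: 6 recurrence vs 5 non-recurrence liver-graft
# expression profiles with six planted candidates (ITGA8, SELE, HFE, CDH26
# down; HLA-DQA2, CD274 up) among 600 null genes, a gene-set collection
# whose designated "cell adhesion molecules" set holds the planted genes,
# a qPCR Ct table for the validation stage, and neighbour lists for the
# correlation stage. Everything is written in the pipeline's plain-text
# input formats under results/data/.

suppressPackageStartupMessages(library(graftDE))

seed <- 1123
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

fx <- simulate_figure2_fixture(seed = seed)
write_count_matrix(fx$counts,
                   "results/data/counts.tsv",
                   "results/data/gene_lengths.tsv",
                   "results/data/groups.tsv")
write_gmt(fx$sets, "results/data/gene_sets.gmt")
write.table(fx$truth, "results/data/truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# Validation cohort: 7 vs 7 recipients plus 4 healthy-donor calibrators,
# 0.1-cycle Ct noise; planted qPCR folds echo two recovered candidates.
ct <- simulate_ct_table(c(HFE = 0.25, CD274 = 4), noise_sd = 0.1,
                        seed = seed + 1)
write_ct_table(ct, "results/data/ct_table.csv")

# Interaction neighbours of the two validated candidates: HFE with its
# iron-handling partners, CD274 with its receptor.
writeLines(c(
  "HFE\tB2M\t0.95", "HFE\tTF\t0.90", "HFE\tTFR2\t0.88", "HFE\tTFRC\t0.85",
  "CD274\tPDCD1\t0.92"
), "results/data/neighbors.tsv")

truth_n <- table(fx$truth$direction)
cat(sprintf(
  "simulated %d genes x %d samples (seed %d): %d planted down, %d planted up, %d null\n",
  nrow(fx$counts$counts), ncol(fx$counts$counts), seed,
  truth_n[["down"]], truth_n[["up"]], truth_n[["null"]]
))
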
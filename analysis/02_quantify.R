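#!/usr/bin/env Rscript
# Stage 2: RPKM quantification.
#
# Reads the gene-level counts written by 01_simulate.R and converts them
# to RPKM (reads per kilobase per million mapped reads), using each
# sample's column sum as the million-mapped denominator.

suppressPackageStartupMessages(library(graftDE))

cm <- read_count_matrix("results/data/counts.tsv",
                        "results/data/gene_lengths.tsv",
                        "results/data/groups.tsv")
expr <- rpkm(cm)
write_expression_matrix(expr, "results/rpkm.tsv")

cat(sprintf("quantified %d genes in %d samples; per-sample mapped totals %s-%s reads\n",
            nrow(expr$rpkm), ncol(expr$rpkm),
            format(min(expr$total_mapped_reads), big.mark = ","),
            format(max(expr$total_mapped_reads), big.mark = ",")))
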
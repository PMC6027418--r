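# In-code fixtures shared across test files.

tiny_count_matrix <- function() {
  count_matrix(
    counts = matrix(
      c(10L, 0L, 100L,
        20L, 5L, 80L,
        2L, 1L, 120L,
        40L, 3L, 90L),
      nrow = 3L,
      dimnames = list(c("g1", "g2", "g3"), c("a1", "a2", "b1", "b2"))
    ),
    gene_lengths = c(g1 = 1000, g2 = 2000, g3 = 500),
    groups = c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  )
}

# Random small count matrix for property tests; caller sets the seed.
random_count_matrix <- function(n_genes, n_a, n_b, max_count = 50L) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  samples <- c(sprintf("a%d", seq_len(n_a)), sprintf("b%d", seq_len(n_b)))
  counts <- matrix(
    sample(0:max_count, n_genes * length(samples), replace = TRUE),
    nrow = n_genes, dimnames = list(genes, samples)
  )
  count_matrix(
    counts,
    gene_lengths = stats::setNames(sample(500:3000, n_genes, TRUE), genes),
    groups = stats::setNames(rep(c("A", "B"), c(n_a, n_b)), samples)
  )
}

write_tiny_pipeline_inputs <- function(dir, cm = NULL, sets = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cm)) cm <- tiny_count_matrix()
  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    lengths = file.path(dir, "lengths.tsv"),
    groups = file.path(dir, "groups.tsv"),
    gene_sets = file.path(dir, "sets.gmt")
  )
  write_count_matrix(cm, paths$counts, paths$lengths, paths$groups)
  if (is.null(sets)) {
    sets <- gene_set_collection(list(
      s1 = rownames(cm$counts)[1:2],
      s2 = rownames(cm$counts)
    ))
  }
  write_gmt(sets, paths$gene_sets)
  paths
}
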
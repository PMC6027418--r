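make_expr <- function(rpkm_mat, groups) {
  # wrap a bare RPKM matrix for stage-level tests (unit library sizes)
  structure(
    list(rpkm = rpkm_mat,
         gene_lengths = stats::setNames(rep(1000, nrow(rpkm_mat)),
                                        rownames(rpkm_mat)),
         groups = groups,
         total_mapped_reads = stats::setNames(rep(1e6, ncol(rpkm_mat)),
                                              colnames(rpkm_mat))),
    class = "expression_matrix"
  )
}

test_that("a 6-vs-5 design yields exactly 30 pairwise lists", {
  sim <- simulate_counts(simulation_config(n_genes = 20, seed = 11))
  pw <- pairwise_lists(rpkm(sim$counts))
  expect_length(pw, 6L * 5L)
  expect_equal(ncol(sim$counts$counts), 11L)
})

test_that("per-pair calls follow the threshold on the pseudocounted ratio", {
  m <- matrix(c(8, 4, 2, 4), nrow = 2,
              dimnames = list(c("g1", "g2"), c("a1", "b1")))
  ex <- make_expr(m, c(a1 = "A", b1 = "B"))
  pw <- pairwise_lists(ex, per_pair_fold_threshold = 2,
                       pseudocount = 1e-12, expression_floor = 0)
  expect_identical(pw[[1]]$up_genes, "g1")
  expect_identical(pw[[1]]$down_genes, character(0))
  expect_equal(unname(pw[[1]]$log2_ratio["g1"]), 2, tolerance = 1e-9)

  # identical expression: both lists empty
  m2 <- matrix(c(5, 5), 1, dimnames = list("g1", c("a1", "b1")))
  pw2 <- pairwise_lists(make_expr(m2, c(a1 = "A", b1 = "B")),
                        expression_floor = 0)
  expect_identical(pw2[[1]]$up_genes, character(0))
  expect_identical(pw2[[1]]$down_genes, character(0))

  expect_error(pairwise_lists(ex, per_pair_fold_threshold = 0.5),
               class = "graftDE_parameter_error")
  expect_error(pairwise_lists(ex, pseudocount = 0),
               class = "graftDE_parameter_error")
})

test_that("the expression floor removes genes quiet in every sample", {
  m <- matrix(c(0.01, 0.02, 5, 7), nrow = 2, byrow = TRUE,
              dimnames = list(c("quiet", "loud"), c("a1", "b1")))
  ex <- make_expr(m, c(a1 = "A", b1 = "B"))
  expect_message(pw <- pairwise_lists(ex), "excluding 1 gene")
  expect_identical(attr(pw, "genes"), "loud")
})

test_that("strict consensus keeps unanimous genes and removes conflicts", {
  # g_up: up in all 4 pairs; g_mix: up in 3, down in 1; g_null: no calls
  m <- matrix(c(
    40, 40, 10, 10,      # g_up
    40, 1000, 10, 300,   # g_mix: up in 3 pairs, down in 1
    10, 10, 10, 10       # g_null
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("g_up", "g_mix", "g_null"),
                  c("a1", "a2", "b1", "b2")))
  ex <- make_expr(m, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  cons <- merge_and_filter(pairwise_lists(ex, pseudocount = 1e-9,
                                          expression_floor = 0))
  tab <- cons$table
  expect_identical(tab$direction[tab$gene == "g_up"], "up")
  expect_identical(tab$direction[tab$gene == "g_mix"], "removed")
  expect_identical(tab$direction[tab$gene == "g_null"], "null")

  # majority mode re-admits the 3-of-4 gene only if conflicts are allowed
  maj <- merge_and_filter(pairwise_lists(ex, pseudocount = 1e-9,
                                         expression_floor = 0),
                          mode = "majority", majority_fraction = 0.75)
  expect_identical(maj$table$direction[maj$table$gene == "g_mix"], "up")
  expect_error(
    merge_and_filter(pairwise_lists(ex, expression_floor = 0),
                     mode = "majority", majority_fraction = 0.4),
    class = "graftDE_parameter_error"
  )
})

test_that("the averaged fold change is the geometric-mean ratio", {
  # one gene, ratios 2 and 8 across the two pairs -> mean log2 = 2, fold 4
  m <- matrix(c(8, 4, 1), 1, dimnames = list("g1", c("a1", "b1", "b2")))
  ex <- make_expr(m, c(a1 = "A", b1 = "B", b2 = "B"))
  cons <- merge_and_filter(pairwise_lists(ex, pseudocount = 1e-12,
                                          expression_floor = 0))
  expect_equal(cons$table$mean_log2_ratio, 2, tolerance = 1e-6)
  expect_equal(cons$table$fold_change, 4, tolerance = 1e-6)

  # linear-scale alternative: arithmetic mean of ratios = 5
  lin <- merge_and_filter(pairwise_lists(ex, pseudocount = 1e-12,
                                         expression_floor = 0),
                          ratio_scale = "linear")
  expect_equal(lin$table$fold_change, 5, tolerance = 1e-6)
})

test_that("candidate selection is strict at the cutoff and sorted", {
  tab <- data.frame(
    gene = c("exact2", "big_up", "big_down", "removed_g"),
    direction = c("up", "up", "down", "removed"),
    n_up = c(4L, 4L, 0L, 2L), n_down = c(0L, 0L, 4L, 2L),
    n_pairs_agreeing = c(4L, 4L, 4L, 2L),
    mean_log2_ratio = c(1, 2.5, -3, 5),
    fold_change = 2^c(1, 2.5, -3, 5),
    stringsAsFactors = FALSE
  )
  res <- structure(list(table = tab, n_pairs = 4L, mode = "strict"),
                   class = "consensus_de")
  sel <- select_candidates(res, fold_cutoff = 2)
  expect_identical(sel$gene, c("big_down", "big_up"))  # |mlr| descending
  expect_false("exact2" %in% sel$gene)                 # strictly more than
  expect_false("removed_g" %in% sel$gene)              # inconsistent genes out
})

test_that("consensus matches the brute-force oracle on random instances", {
  set.seed(13)
  for (i in 1:200) {
    n_g <- sample(2:10, 1)
    n_a <- sample(1:2, 1)
    n_b <- sample(1:2, 1)
    cm <- random_count_matrix(n_g, n_a, n_b, max_count = 30L)
    if (any(colSums(cm$counts) == 0)) next
    ex <- rpkm(cm)
    cons <- merge_and_filter(pairwise_lists(ex, expression_floor = 0))
    orc <- oracle_consensus(ex$rpkm, ex$groups)
    expect_identical(cons$table$direction, orc$direction)
    expect_equal(cons$table$mean_log2_ratio, orc$mean_log2_ratio,
                 tolerance = 1e-12)
  }
})

test_that("swapping group labels negates ratios and swaps directions", {
  set.seed(14)
  for (i in 1:50) {
    cm <- random_count_matrix(sample(3:8, 1), 2, 2, max_count = 40L)
    if (any(colSums(cm$counts) == 0)) next
    ex <- rpkm(cm)
    swapped <- ex
    swapped$groups[] <- ifelse(ex$groups == "A", "B", "A")
    a <- merge_and_filter(pairwise_lists(ex, expression_floor = 0))
    b <- merge_and_filter(pairwise_lists(swapped, expression_floor = 0))
    expect_equal(b$table$mean_log2_ratio, -a$table$mean_log2_ratio,
                 tolerance = 1e-12)
    map <- c(up = "down", down = "up", removed = "removed", null = "null")
    expect_identical(b$table$direction, unname(map[a$table$direction]))
  }
})

test_that("raising thresholds never grows the calls", {
  set.seed(15)
  cm <- random_count_matrix(12, 2, 2, max_count = 60L)
  ex <- rpkm(cm)
  sizes <- sapply(c(1.5, 2, 3, 5), function(thr) {
    pw <- pairwise_lists(ex, per_pair_fold_threshold = thr,
                         expression_floor = 0)
    sum(sapply(pw, function(p) length(p$up_genes) + length(p$down_genes)))
  })
  expect_true(all(diff(sizes) <= 0))

  cons <- merge_and_filter(pairwise_lists(ex, expression_floor = 0))
  n_sel <- sapply(c(1, 2, 4, 8), function(fc)
    nrow(select_candidates(cons, fc)))
  expect_true(all(diff(n_sel) <= 0))
})
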
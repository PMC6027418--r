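test_that("the simulator is a pure function of its config", {
  cfg <- simulation_config(n_genes = 50, planted_effects = c(gA = 4),
                           seed = 101)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_counts(simulation_config(n_genes = 50,
                                          planted_effects = c(gA = 4),
                                          seed = 102))
  expect_false(identical(a$counts$counts, c_$counts$counts))
})

test_that("the default design has 11 samples: 6 recurrence vs 5 not", {
  sim <- simulate_counts(simulation_config(n_genes = 10, seed = 1))
  expect_equal(ncol(sim$counts$counts), 11L)
  expect_equal(sum(sim$counts$groups == "A"), 6L)
  expect_equal(sum(sim$counts$groups == "B"), 5L)
})

test_that("a null config plants no DE genes and dispersion 0 is Poisson", {
  cfg <- simulation_config(n_genes = 30, dispersion = 0, seed = 5)
  sim <- simulate_counts(cfg)
  expect_true(all(sim$truth$direction == "null"))
  expect_true(all(sim$truth$true_fold == 1))
})

test_that("config validation rejects impossible plants", {
  expect_error(simulation_config(n_genes = 10,
                                 planted_effects = c(g = -2), seed = 1),
               class = "graftDE_parameter_error")
  expect_error(
    simulation_config(n_genes = 2,
                      planted_effects = c(a = 2, b = 2, c = 2), seed = 1),
    class = "graftDE_parameter_error"
  )
})

test_that("the six-candidate fixture plants 4 down and 2 up in its set", {
  fx <- simulate_figure2_fixture(seed = 3)
  planted <- fx$truth[fx$truth$direction != "null", ]
  expect_equal(nrow(planted), 6L)
  expect_setequal(planted$gene[planted$direction == "down"],
                  c("ITGA8", "SELE", "HFE", "CDH26"))
  expect_setequal(planted$gene[planted$direction == "up"],
                  c("HLA-DQA2", "CD274"))
  expect_true(all(planted$true_fold[planted$direction == "down"] <= 1 / 4))
  expect_true(all(planted$true_fold[planted$direction == "up"] >= 4))
  expect_gte(sum(fx$truth$direction == "null"), 500L)
  expect_true(all(planted$gene %in% fx$sets[["cell adhesion molecules"]]))
})

test_that("Ct simulation inverts 2^-ddCt exactly at zero noise", {
  tab <- simulate_ct_table(c(gene_x = 4), noise_sd = 0, seed = 9)
  rel <- ddct(tab, "gene_x")
  rec <- rel$samples$group == "recurrence"
  expect_equal(unique(rel$samples$delta_delta_ct[rec]), -2)
  expect_equal(unique(rel$samples$relative_level[rec]), 4)
  expect_equal(unique(rel$samples$relative_level[!rec]), 1)

  flat <- simulate_ct_table(c(g1 = 1, g2 = 1), noise_sd = 0, seed = 9)
  for (g in c("g1", "g2")) {
    expect_equal(ddct(flat, g)$samples$relative_level,
                 rep(1, ncol(flat$ct)))
  }
})

test_that("noisy Ct simulation recovers the planted fold within 15%", {
  # 0.2-cycle noise, 50 samples per cohort: the group geometric mean of
  # relative levels estimates the planted fold
  tab <- simulate_ct_table(c(g = 3), noise_sd = 0.2, seed = 21,
                           n_recurrence = 50, n_non_recurrence = 50,
                           n_calibrator = 50)
  rel <- ddct(tab, "g")
  rec <- rel$samples$group == "recurrence"
  est <- 2^mean(log2(rel$samples$relative_level[rec]))
  expect_lt(abs(est - 3) / 3, 0.15)
})
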
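worked_ct_table <- function() {
  # patient: target 24 / reference 20; calibrators: target 26 / reference 20
  m <- matrix(c(24, 20,
                26, 20,
                26, 20), nrow = 2,
              dimnames = list(c("HFE", "ACTB"), c("p1", "d1", "d2")))
  ct_table(m, c(p1 = "recurrence", d1 = "calibrator", d2 = "calibrator"),
           "ACTB")
}

test_that("ddct reproduces the Livak worked example", {
  rel <- ddct(worked_ct_table(), "HFE")
  p1 <- rel$samples[rel$samples$sample == "p1", ]
  expect_equal(p1$delta_ct, 4)
  expect_equal(p1$delta_delta_ct, -2)
  expect_equal(p1$relative_level, 4)
  expect_equal(rel$calibrator_baseline, 6)
})

test_that("a sample identical to the calibrator mean has level 1", {
  m <- matrix(c(26, 20, 26, 20), 2,
              dimnames = list(c("HFE", "ACTB"), c("p1", "d1")))
  tab <- ct_table(m, c(p1 = "recurrence", d1 = "calibrator"), "ACTB")
  expect_equal(ddct(tab, "HFE")$samples$relative_level, c(1, 1))
})

test_that("relative levels are invariant to per-sample Ct shifts", {
  tab <- worked_ct_table()
  shifted <- tab$ct
  shifted[, "p1"] <- shifted[, "p1"] + 3.7   # e.g. input-amount offset
  tab2 <- ct_table(shifted, tab$groups, "ACTB")
  expect_equal(ddct(tab2, "HFE")$samples$relative_level,
               ddct(tab, "HFE")$samples$relative_level)
})

test_that("calibrators self-normalize to geometric mean exactly 1", {
  set.seed(31)
  m <- rbind(HFE = 26 + rnorm(6, 0, 0.5), ACTB = 20 + rnorm(6, 0, 0.3))
  colnames(m) <- sprintf("d%d", 1:6)
  tab <- ct_table(m, stats::setNames(rep("calibrator", 6), colnames(m)),
                  "ACTB")
  rel <- ddct(tab, "HFE")
  expect_equal(exp(mean(log(rel$samples$relative_level))), 1,
               tolerance = 1e-12)
})

test_that("samples with missing Ct are excluded with a message", {
  m <- matrix(c(24, 20, NA, 20, 26, 20), 2,
              dimnames = list(c("HFE", "ACTB"), c("p1", "p2", "d1")))
  tab <- ct_table(m, c(p1 = "recurrence", p2 = "recurrence",
                       d1 = "calibrator"), "ACTB")
  expect_message(rel <- ddct(tab, "HFE"), "excluding 1 sample")
  expect_setequal(rel$samples$sample, c("p1", "d1"))

  expect_error(ddct(tab, "absent"), class = "graftDE_parameter_error")
  m2 <- matrix(c(24, 20, NA, 20), 2,
               dimnames = list(c("HFE", "ACTB"), c("p1", "d1")))
  tab2 <- ct_table(m2, c(p1 = "recurrence", d1 = "calibrator"), "ACTB")
  expect_error(suppressMessages(ddct(tab2, "HFE")),
               class = "graftDE_design_error")
})

test_that("group comparison uses the exact Mann-Whitney null at small n", {
  rel <- structure(list(
    samples = data.frame(
      sample = sprintf("s%d", 1:6),
      group = rep(c("recurrence", "non-recurrence"), each = 3),
      relative_level = c(1, 2, 3, 4, 5, 6),
      delta_ct = NA, delta_delta_ct = NA
    ),
    gene = "g", reference_gene = "ref", calibrator_baseline = 0
  ), class = "relative_expression")
  cmp <- compare_groups(rel, "mann_whitney")
  expect_equal(cmp$p_value, 0.1)
  expect_equal(cmp$p_value,
               oracle_mann_whitney_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(unname(cmp$statistic), 0)

  # identical groups: no evidence of a difference
  rel$samples$relative_level <- rep(c(1, 2, 3), 2)
  expect_equal(compare_groups(rel, "mann_whitney")$p_value, 1)

  rel$samples$group <- c(rep("recurrence", 5), "non-recurrence")
  expect_error(compare_groups(rel), class = "graftDE_design_error")
})

test_that("a planted 4-fold difference is detected at 0.1-cycle noise", {
  # 7 vs 7 validation-cohort design; power over 20 seeds
  hits <- sum(sapply(1:20, function(s) {
    tab <- simulate_ct_table(c(g = 4), noise_sd = 0.1, seed = 1000 + s)
    compare_groups(ddct(tab, "g"), "mann_whitney")$p_value < 0.05
  }))
  expect_gte(hits, 19L)
})
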
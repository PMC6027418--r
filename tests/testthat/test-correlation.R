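test_that("Pearson correlation hits the exact cases", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(4, 3, 2, 1))$r, -1)
  expect_error(pearson_cor(c(1, 2, 3), c(5, 5, 5)),
               class = "graftDE_undefined_correlation")
  expect_error(pearson_cor(c(1, 2), c(1, 2)),
               class = "graftDE_parameter_error")
  # pairwise deletion of incomplete pairs
  res <- pearson_cor(c(1, 2, 3, NA, 5), c(2, 4, 6, 8, NA))
  expect_equal(res$n, 3L)
  expect_equal(res$r, 1)
})

test_that("Pearson is symmetric and affine-invariant", {
  set.seed(41)
  x <- rnorm(20); y <- rnorm(20)
  a <- pearson_cor(x, y)
  b <- pearson_cor(y, x)
  expect_equal(a$r, b$r)
  expect_equal(a$p_value, b$p_value)
  c_ <- pearson_cor(3 * x + 7, y)
  expect_equal(c_$r, a$r, tolerance = 1e-12)
})

test_that("correlation panels call planted co-expression positively", {
  set.seed(43)
  n <- 43  # recipient-cohort size the panels emulate
  focal <- 2^rnorm(n, 4, 1)
  expr <- rbind(
    HFE = focal,
    B2M = focal * 2^rnorm(n, 0, 0.2),   # tightly co-expressed
    TFRC = 2^rnorm(n, 4, 1),            # independent
    COPY = focal
  )
  colnames(expr) <- sprintf("s%02d", 1:n)
  panel <- correlation_panel(expr, "HFE", c("B2M", "TFRC", "COPY"))
  expect_identical(panel$verdict[panel$neighbor == "B2M"],
                   "positively correlated")
  expect_gt(panel$r[panel$neighbor == "B2M"], 0.9)
  expect_equal(panel$r[panel$neighbor == "COPY"], 1)
  expect_identical(panel$verdict[panel$neighbor == "COPY"],
                   "positively correlated")

  expect_error(correlation_panel(expr, "missing", "B2M"),
               class = "graftDE_parameter_error")
  expect_warning(p2 <- correlation_panel(expr, "HFE", c("B2M", "ghost")),
                 "not measured")
  expect_identical(p2$neighbor, "B2M")
})

test_that("independent neighbours are rarely called correlated", {
  calls <- sapply(1:50, function(s) {
    set.seed(2000 + s)
    n <- 43
    expr <- rbind(F = 2^rnorm(n, 4, 1), N = 2^rnorm(n, 4, 1))
    colnames(expr) <- sprintf("s%d", 1:n)
    correlation_panel(expr, "F", "N")$verdict
  })
  expect_gte(mean(calls == "not correlated"), 0.9)
})

test_that("Fisher 2x2 matches hand-worked and degenerate cases", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 3, 0, 4), 2)), 1)
  expect_error(fisher_exact_2x2(matrix(c(1, 2, 3, -1), 2)),
               class = "graftDE_parameter_error")
})

test_that("Fisher 2x2 agrees with margin enumeration up to total 30", {
  set.seed(47)
  for (i in 1:100) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (sum(tab) < 1 || sum(tab) > 30) next
    expect_equal(fisher_exact_2x2(tab), oracle_fisher_p(tab),
                 tolerance = 1e-9,
                 info = paste(tab, collapse = ","))
  }
})
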
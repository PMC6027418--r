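#' Pearson correlation with two-sided t-based p-value
#'
#' Product-moment correlation after pairwise deletion of missing values;
#' the p-value comes from the t transform with n - 2 degrees of freedom
#' (via [stats::cor.test()]). At least 3 complete pairs and non-zero
#' variance on both sides are required.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p_value` and `n` (complete pairs used).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) param_error("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    param_error("need >= 3 complete pairs for a correlation")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_graftde("correlation undefined: zero variance",
                 "graftDE_undefined_correlation")
  }
  ht <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ht$estimate), p_value = unname(ht$p.value), n = length(x))
}

#' Correlate a focal gene against its interaction neighbours
#'
#' One Pearson correlation per neighbour across the samples where both
#' genes are measured, mirroring how candidate genes are checked against
#' their interaction partners. Expression is log2-transformed by default
#' (fold structure dominates both RPKM and 2^-ddCt levels); a neighbour is
#' called `positively correlated` when r > 0 and p < `alpha`. No
#' multiple-testing correction is applied by default since panels are
#' small; set `adjust = TRUE` for Benjamini-Hochberg across neighbours.
#'
#' @param expr Numeric matrix, genes in rows and samples in columns —
#'   an `expression_matrix`'s `rpkm` slot, or relative qPCR levels
#'   assembled per gene.
#' @param focal Focal gene id (must be a row of `expr`).
#' @param neighbors Character vector of neighbour gene ids, or one element
#'   of [read_neighbor_lists()] output (its `neighbor` column is used).
#'   Neighbours absent from `expr` are skipped with a warning.
#' @param alpha Significance level for the verdict. Default 0.05.
#' @param log2_scale Correlate on log2(expr + `log_offset`)? Default TRUE.
#' @param log_offset Offset used before the log transform. Default 0.1.
#' @param adjust Apply BH adjustment across neighbours before the verdict?
#' @return A `correlation_panel`: data frame with one row per tested
#'   neighbour (`neighbor`, `n`, `r`, `p_value`, `verdict`); the focal
#'   gene and alpha ride along as attributes.
#' @export
correlation_panel <- function(expr, focal, neighbors, alpha = 0.05,
                              log2_scale = TRUE, log_offset = 0.1,
                              adjust = FALSE) {
  if (inherits(expr, "expression_matrix")) expr <- expr$rpkm
  if (!is.matrix(expr) || is.null(rownames(expr))) {
    param_error("expr must be a genes x samples matrix with rownames")
  }
  if (is.data.frame(neighbors)) neighbors <- neighbors$neighbor
  neighbors <- unique(as.character(neighbors))
  if (!focal %in% rownames(expr)) {
    param_error(sprintf("focal gene %s absent from expression matrix", focal))
  }
  missing <- setdiff(neighbors, rownames(expr))
  if (length(missing)) {
    warning(sprintf("skipping %d neighbour(s) not measured: %s",
                    length(missing), paste(missing, collapse = ", ")))
    neighbors <- setdiff(neighbors, missing)
  }
  if (!length(neighbors)) param_error("no measurable neighbours")
  vals <- if (log2_scale) log2(expr + log_offset) else expr
  rows <- lapply(neighbors, function(nb) {
    res <- pearson_cor(vals[focal, ], vals[nb, ])
    data.frame(neighbor = nb, n = res$n, r = res$r, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p_for_verdict <- if (adjust) stats::p.adjust(out$p_value, "BH") else out$p_value
  if (adjust) out$adjusted_p <- p_for_verdict
  out$verdict <- ifelse(
    out$r > 0 & p_for_verdict < alpha, "positively correlated",
    ifelse(out$r < 0 & p_for_verdict < alpha, "negatively correlated",
           "not correlated")
  )
  rownames(out) <- NULL
  structure(out, focal = focal, alpha = alpha, class = c("correlation_panel",
                                                         "data.frame"))
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided exact p-value, summing the probabilities of all tables with
#' the observed margins that are no more probable than the observed one
#' (via [stats::fisher.test()]). Used for the categorical cohort-table
#' comparisons.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided exact p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))  # 2/choose(10,5) ~ 0.00794
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == c(2L, 2L))) {
    param_error("table must be a 2x2 matrix")
  }
  if (any(is.na(table)) || any(table < 0) || any(table != round(table))) {
    param_error("table entries must be non-negative integers")
  }
  if (sum(table) < 1) param_error("grand total must be >= 1")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(1)  # degenerate margin: only one table is possible
  }
  unname(stats::fisher.test(table, alternative = "two.sided")$p.value)
}
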
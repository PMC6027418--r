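#' 2^-ddCt relative quantification of a target gene
#'
#' Livak relative quantification against an internal reference gene and a
#' calibrator cohort (healthy-donor livers in the experiments this
#' models). Per sample,
#' \deqn{\Delta Ct = Ct_{target} - Ct_{reference}}
#' the calibrator baseline is the arithmetic mean of calibrator
#' \eqn{\Delta Ct} values (the Livak convention; equivalently a geometric
#' mean on the linear expression scale),
#' \deqn{\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{cal}, \qquad
#'       \text{relative level} = 2^{-\Delta\Delta Ct}.}
#' `baseline_scale = "linear"` instead averages the calibrators'
#' \eqn{2^{-\Delta Ct}} on the linear scale; the two differ by a Jensen
#' gap whenever calibrators vary.
#'
#' Samples missing the target or reference Ct are excluded with a message.
#' PCR efficiency is fixed at 2 (perfect doubling); no efficiency-corrected
#' model is offered.
#'
#' @param ct A [ct_table].
#' @param target_gene Gene whose expression is quantified.
#' @param reference_gene Internal normalisation control; defaults to the
#'   table's designated reference.
#' @param baseline_scale `"ct"` (default, mean calibrator delta-Ct) or
#'   `"linear"`.
#' @return A `relative_expression` object: data frame `samples` with
#'   columns `sample`, `group`, `delta_ct`, `delta_delta_ct`,
#'   `relative_level`, plus fields `gene`, `reference_gene` and
#'   `calibrator_baseline` (on the delta-Ct scale).
#' @examples
#' m <- matrix(c(24, 20, 26, 20), 2, 2,
#'             dimnames = list(c("HFE", "ACTB"), c("p1", "d1")))
#' tab <- ct_table(m, c(p1 = "recurrence", d1 = "calibrator"), "ACTB")
#' ddct(tab, "HFE")$samples  # p1: ddCt = -2, relative level = 4
#' @export
ddct <- function(ct, target_gene, reference_gene = ct$reference_gene,
                 baseline_scale = c("ct", "linear")) {
  stopifnot(inherits(ct, "ct_table"))
  baseline_scale <- match.arg(baseline_scale)
  if (!target_gene %in% rownames(ct$ct)) {
    param_error(sprintf("target gene %s absent from Ct table", target_gene))
  }
  if (!reference_gene %in% rownames(ct$ct)) {
    param_error(sprintf("reference gene %s absent from Ct table", reference_gene))
  }
  d_ct <- ct$ct[target_gene, ] - ct$ct[reference_gene, ]
  usable <- !is.na(d_ct)
  if (any(!usable)) {
    message(sprintf("ddct(%s): excluding %d sample(s) with missing Ct",
                    target_gene, sum(!usable)))
  }
  d_ct <- d_ct[usable]
  groups <- ct$groups[usable]
  cal <- groups == "calibrator"
  if (!any(cal)) {
    design_error(sprintf(
      "no calibrator sample has complete Ct for %s and %s",
      target_gene, reference_gene
    ))
  }
  baseline <- if (baseline_scale == "ct") {
    mean(d_ct[cal])
  } else {
    -log2(mean(2^(-d_ct[cal])))
  }
  dd_ct <- d_ct - baseline
  structure(
    list(
      samples = data.frame(
        sample = names(d_ct), group = unname(groups),
        delta_ct = unname(d_ct), delta_delta_ct = unname(dd_ct),
        relative_level = unname(2^(-dd_ct)),
        stringsAsFactors = FALSE
      ),
      gene = target_gene, reference_gene = reference_gene,
      calibrator_baseline = baseline, baseline_scale = baseline_scale
    ),
    class = "relative_expression"
  )
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf(
    "relative_expression: %s vs %s, %d samples, calibrator baseline dCt = %.3f\n",
    x$gene, x$reference_gene, nrow(x$samples), x$calibrator_baseline
  ))
  invisible(x)
}

#' Compare relative expression between recurrence and non-recurrence groups
#'
#' Two-sided comparison of per-sample relative levels. The default
#' Mann-Whitney U test uses the exact permutation distribution when the
#' combined sample size is at most 12 and there are no ties, and the
#' normal approximation with tie correction otherwise; Welch's t-test is
#' available as the parametric alternative. Both act on log2 relative
#' levels for the t-test (fold structure is multiplicative) and on raw
#' levels for the rank test (rank-invariant either way).
#'
#' @param rel A `relative_expression` from [ddct()].
#' @param test `"mann_whitney"` (default) or `"t"`.
#' @return List with `gene`, `test`, `p_value`, `statistic`, and per-group
#'   `n`, `mean` and `median` of relative levels.
#' @export
compare_groups <- function(rel, test = c("mann_whitney", "t")) {
  stopifnot(inherits(rel, "relative_expression"))
  test <- match.arg(test)
  s <- rel$samples
  x <- s$relative_level[s$group == "recurrence"]
  y <- s$relative_level[s$group == "non-recurrence"]
  if (length(x) < 2L || length(y) < 2L) {
    design_error("each compared group needs >= 2 samples")
  }
  if (test == "mann_whitney") {
    exact <- (length(x) + length(y)) <= 12L && !anyDuplicated(c(x, y))
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = !exact)
    )
  } else {
    ht <- stats::t.test(log2(x), log2(y))
  }
  list(
    gene = rel$gene, test = test,
    p_value = unname(ht$p.value), statistic = unname(ht$statistic),
    recurrence = list(n = length(x), mean = mean(x), median = stats::median(x)),
    non_recurrence = list(n = length(y), mean = mean(y), median = stats::median(y))
  )
}
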
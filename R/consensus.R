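#' Per-pair differential-expression lists
#'
#' The first stage of the consensus procedure: every recurrence (group A)
#' sample is compared against every non-recurrence (group B) sample
#' individually. For each ordered (A, B) pair, the per-gene expression
#' ratio is \eqn{(RPKM_A + c) / (RPKM_B + c)} with pseudocount \eqn{c}; a
#' gene enters the pair's up list when the ratio is at least the per-pair
#' fold threshold and the down list when it is at most its reciprocal.
#' A 6-vs-5 design therefore yields 30 pairwise lists.
#'
#' Genes whose RPKM stays below `expression_floor` in every sample are
#' excluded before comparison (their ratios are pseudocount noise); the
#' number dropped is reported via `message()`.
#'
#' @param expr An `expression_matrix` from [rpkm()].
#' @param per_pair_fold_threshold Fold change calling a gene up/down within
#'   a single pair; must be `>= 1`. Default 2.
#' @param pseudocount Positive RPKM offset stabilising ratios at zero
#'   expression. Default 0.1.
#' @param expression_floor Minimum RPKM a gene must reach in at least one
#'   sample to be compared at all. Default 0.1; set to 0 to disable.
#' @return A `pairwise_lists` object: list of per-pair records, each with
#'   `pair` (A sample, B sample), `up_genes`, `down_genes` and the full
#'   per-gene `log2_ratio` vector; attributes carry the parameters and the
#'   retained gene universe.
#' @export
pairwise_lists <- function(expr, per_pair_fold_threshold = 2,
                           pseudocount = 0.1, expression_floor = 0.1) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!is.numeric(per_pair_fold_threshold) || per_pair_fold_threshold < 1) {
    param_error("per_pair_fold_threshold must be >= 1")
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    param_error("pseudocount must be > 0")
  }
  a_samples <- names(expr$groups)[expr$groups == "A"]
  b_samples <- names(expr$groups)[expr$groups == "B"]
  if (!length(a_samples) || !length(b_samples)) {
    design_error("both groups must be non-empty")
  }

  vals <- expr$rpkm
  expressed <- rowSums(vals >= expression_floor) > 0L
  if (any(!expressed)) {
    message(sprintf("excluding %d gene(s) below the %.3g-RPKM expression floor",
                    sum(!expressed), expression_floor))
    vals <- vals[expressed, , drop = FALSE]
  }

  log2_thr <- log2(per_pair_fold_threshold)
  lv <- log2(vals + pseudocount)
  genes <- rownames(vals)
  out <- vector("list", length(a_samples) * length(b_samples))
  i <- 0L
  for (a in a_samples) {
    for (b in b_samples) {
      i <- i + 1L
      lr <- lv[, a] - lv[, b]
      out[[i]] <- list(
        pair = c(A = a, B = b),
        up_genes = genes[lr >= log2_thr],
        down_genes = genes[lr <= -log2_thr],
        log2_ratio = stats::setNames(lr, genes)
      )
    }
  }
  structure(out, class = "pairwise_lists",
            genes = genes,
            per_pair_fold_threshold = per_pair_fold_threshold,
            pseudocount = pseudocount,
            expression_floor = expression_floor)
}

#' @export
print.pairwise_lists <- function(x, ...) {
  cat(sprintf("pairwise_lists: %d (A, B) sample pairs over %d genes\n",
              length(x), length(attr(x, "genes"))))
  invisible(x)
}

#' Merge per-pair lists into a consensus call with consistency filtering
#'
#' Merges the per-pair up/down lists and removes genes whose direction of
#' change is inconsistent across pairs. In `strict` mode (the default) a
#' gene is kept as up (down) only when every pair calls it up (down) and no
#' pair calls the opposite; in `majority` mode it is kept when at least
#' `majority_fraction` of the pairs agree on a direction and at most
#' `1 - majority_fraction` call the opposite. Genes with some call but no
#' consensus are `removed`; genes no pair called at all are `null`.
#'
#' The average expression difference is the arithmetic mean of per-pair
#' log2 ratios — the log of the geometric-mean ratio, which makes A/B and
#' B/A exactly antisymmetric. `ratio_scale = "linear"` instead averages the
#' raw ratios (arithmetic mean) for fidelity comparisons.
#'
#' @param lists A `pairwise_lists` object.
#' @param mode `"strict"` or `"majority"`.
#' @param majority_fraction Agreement fraction for majority mode, in
#'   (0.5, 1].
#' @param ratio_scale `"log2"` (default, geometric-mean ratio) or
#'   `"linear"` (arithmetic mean of ratios).
#' @return A `consensus_de` object: `table` is a data frame with one row
#'   per gene (`gene`, `direction`, `n_up`, `n_down`, `n_pairs_agreeing`,
#'   `mean_log2_ratio`, `fold_change`); `log2_ratios` is the genes x pairs
#'   ratio matrix; `n_pairs` the pair count.
#' @export
merge_and_filter <- function(lists, mode = c("strict", "majority"),
                             majority_fraction = 0.9,
                             ratio_scale = c("log2", "linear")) {
  stopifnot(inherits(lists, "pairwise_lists"), length(lists) >= 1L)
  mode <- match.arg(mode)
  ratio_scale <- match.arg(ratio_scale)
  if (mode == "majority" &&
      (majority_fraction <= 0.5 || majority_fraction > 1)) {
    param_error("majority_fraction must lie in (0.5, 1]")
  }
  genes <- attr(lists, "genes")
  n_pairs <- length(lists)

  ratios <- vapply(lists, function(p) p$log2_ratio[genes], numeric(length(genes)))
  ratios <- matrix(ratios, nrow = length(genes),
                   dimnames = list(genes, vapply(lists, function(p)
                     paste(p$pair, collapse = "_vs_"), character(1))))

  n_up <- rowSums(matrix(
    vapply(lists, function(p) genes %in% p$up_genes, logical(length(genes))),
    nrow = length(genes)
  ))
  n_down <- rowSums(matrix(
    vapply(lists, function(p) genes %in% p$down_genes, logical(length(genes))),
    nrow = length(genes)
  ))

  direction <- rep("null", length(genes))
  any_call <- (n_up + n_down) > 0L
  if (mode == "strict") {
    is_up <- n_up == n_pairs & n_down == 0L
    is_down <- n_down == n_pairs & n_up == 0L
  } else {
    need <- majority_fraction * n_pairs
    allow_opp <- (1 - majority_fraction) * n_pairs
    is_up <- n_up >= need & n_down <= allow_opp
    is_down <- n_down >= need & n_up <= allow_opp
    both <- is_up & is_down   # only possible at degenerate fractions
    is_up[both] <- is_down[both] <- FALSE
  }
  direction[any_call] <- "removed"
  direction[is_up] <- "up"
  direction[is_down] <- "down"

  mean_l2 <- rowMeans(ratios)
  if (ratio_scale == "linear") {
    fold <- rowMeans(2^ratios)
    mean_l2 <- log2(fold)
  } else {
    fold <- 2^mean_l2
  }

  tab <- data.frame(
    gene = genes,
    direction = direction,
    n_up = n_up,
    n_down = n_down,
    n_pairs_agreeing = pmax(n_up, n_down),
    mean_log2_ratio = unname(mean_l2),
    fold_change = unname(fold),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(
    list(table = tab, log2_ratios = ratios, n_pairs = n_pairs,
         mode = mode, majority_fraction = majority_fraction,
         ratio_scale = ratio_scale,
         per_pair_fold_threshold = attr(lists, "per_pair_fold_threshold"),
         pseudocount = attr(lists, "pseudocount")),
    class = "consensus_de"
  )
}

#' @export
print.consensus_de <- function(x, ...) {
  d <- table(factor(x$table$direction, c("up", "down", "removed", "null")))
  cat(sprintf(
    "consensus_de (%s mode, %d pairs): %d up, %d down, %d removed as inconsistent, %d uncalled\n",
    x$mode, x$n_pairs, d[["up"]], d[["down"]], d[["removed"]], d[["null"]]
  ))
  invisible(x)
}

#' Select candidate genes exceeding a consensus fold-change cutoff
#'
#' Keeps consistently called genes whose averaged fold change is strictly
#' more than `fold_cutoff` (up candidates) or strictly less than
#' `1/fold_cutoff` (down candidates) — "more than two-fold" is a strict
#' inequality, so a gene at exactly the cutoff is not selected.
#'
#' @param result A `consensus_de` object.
#' @param fold_cutoff Consensus fold cutoff, `>= 1`. Default 2.
#' @return Data frame of selected genes (columns as in `result$table`),
#'   sorted by descending `|mean_log2_ratio|`, ties broken by gene id.
#' @export
select_candidates <- function(result, fold_cutoff = 2) {
  stopifnot(inherits(result, "consensus_de"))
  if (!is.numeric(fold_cutoff) || fold_cutoff < 1) {
    param_error("fold_cutoff must be >= 1")
  }
  tab <- result$table
  keep_up <- tab$direction == "up" & tab$fold_change > fold_cutoff
  keep_down <- tab$direction == "down" & tab$fold_change < 1 / fold_cutoff
  out <- tab[keep_up | keep_down, , drop = FALSE]
  out <- out[order(-abs(out$mean_log2_ratio), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full consensus DE procedure in one call
#'
#' Convenience wrapper: [rpkm()] then [pairwise_lists()],
#' [merge_and_filter()] and [select_candidates()].
#'
#' @param counts A [count_matrix].
#' @param per_pair_fold_threshold,pseudocount,expression_floor
#'   See [pairwise_lists()].
#' @param mode,majority_fraction,ratio_scale See [merge_and_filter()].
#' @param fold_cutoff See [select_candidates()].
#' @return List with `expression`, `pairwise`, `consensus` and
#'   `candidates`.
#' @export
consensus_de_pipeline <- function(counts, per_pair_fold_threshold = 2,
                                  pseudocount = 0.1, expression_floor = 0.1,
                                  mode = "strict", majority_fraction = 0.9,
                                  ratio_scale = "log2", fold_cutoff = 2) {
  expr <- rpkm(counts)
  pw <- pairwise_lists(expr, per_pair_fold_threshold, pseudocount,
                       expression_floor)
  cons <- merge_and_filter(pw, mode = mode,
                           majority_fraction = majority_fraction,
                           ratio_scale = ratio_scale)
  cand <- select_candidates(cons, fold_cutoff)
  list(expression = expr, pairwise = pw, consensus = cons, candidates = cand)
}
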
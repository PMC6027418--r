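#' Hypergeometric upper-tail probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(`N`, `K`, `n`): the
#' chance that a size-`n` draw from a universe of `N` genes, `K` of which
#' belong to the set, overlaps the set in at least `k` genes. Evaluated via
#' [stats::phyper()], whose tail accumulation works on the log scale, so
#' tiny tails are exact rather than underflowing.
#'
#' @param N Universe size.
#' @param K Gene-set size within the universe.
#' @param n Query size.
#' @param k Observed overlap.
#' @return Upper-tail probability in (0, 1].
#' @examples
#' hypergeom_upper_tail(10, 5, 4, 4)  # choose(5,4)/choose(10,4) = 5/210
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  for (v in list(N = N, K = K, n = n, k = k)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v)) {
      param_error("N, K, n, k must be single non-negative integers")
    }
  }
  if (K > N || n > N) param_error("K and n must not exceed N")
  if (k > min(K, n)) param_error("k must not exceed min(K, n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation of a query gene list
#'
#' Tests each supplied gene set for enrichment among the query genes (for
#' instance the consensus DE candidates) with the one-sided hypergeometric
#' upper tail — equivalently Fisher's exact test on the enrichment side —
#' followed by Benjamini-Hochberg adjustment across sets. Set membership
#' is intersected with the universe before testing; query genes outside
#' the universe are dropped with a warning.
#'
#' @param query_genes Character vector of query gene ids.
#' @param sets A `gene_set_collection` (see [read_gmt()]).
#' @param universe Character vector: the gene universe. A natural choice is
#'   every gene surviving the expression floor in [pairwise_lists()].
#' @return Data frame with one row per set, sorted by ascending `p_value`
#'   (ties by set name): `set`, `universe_size`, `set_size`, `query_size`,
#'   `overlap`, `p_value`, `adjusted_p`, `overlap_genes`
#'   (comma-separated).
#' @export
enrich <- function(query_genes, sets, universe) {
  stopifnot(inherits(sets, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) param_error("universe must be non-empty")
  query_genes <- unique(as.character(query_genes))
  outside <- setdiff(query_genes, universe)
  if (length(outside)) {
    warning(sprintf("dropping %d query gene(s) outside the universe: %s",
                    length(outside),
                    paste(utils::head(outside, 5L), collapse = ", ")))
    query_genes <- intersect(query_genes, universe)
  }
  if (!length(query_genes)) {
    warning("empty query; returning no enrichment results")
    return(data.frame(
      set = character(), universe_size = integer(), set_size = integer(),
      query_size = integer(), overlap = integer(), p_value = numeric(),
      adjusted_p = numeric(), overlap_genes = character()
    ))
  }
  N <- length(universe)
  n <- length(query_genes)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    hit <- intersect(query_genes, members)
    data.frame(
      set = nm, universe_size = N, set_size = length(members),
      query_size = n, overlap = length(hit),
      p_value = hypergeom_upper_tail(N, length(members), n, length(hit)),
      overlap_genes = paste(sort(hit), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set),
             c("set", "universe_size", "set_size", "query_size", "overlap",
               "p_value", "adjusted_p", "overlap_genes")]
  rownames(out) <- NULL
  out
}
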
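#' RPKM expression levels from read counts
#'
#' Reads per kilobase of transcript per million mapped reads:
#' \deqn{RPKM_{gs} = \frac{10^9 \, c_{gs}}{L_g \, T_s}}
#' where \eqn{c_{gs}} is the read count of gene \eqn{g} in sample \eqn{s},
#' \eqn{L_g} the gene length in bp and \eqn{T_s} the per-sample mapped-read
#' total. By default \eqn{T_s} is the column sum of the count matrix (the
#' gene-assigned total); a per-sample override lets callers supply
#' genome-wide mapped totals instead, since both conventions exist. No
#' pseudocount is applied here — zeros stay zero and are handled at ratio
#' time.
#'
#' @param counts A [count_matrix].
#' @param total_mapped_reads Optional named numeric vector overriding the
#'   per-sample million-mapped denominator (one positive value per sample).
#' @return An `expression_matrix`: list with `rpkm` (genes x samples),
#'   `gene_lengths`, `groups` and `total_mapped_reads`.
#' @examples
#' cm <- count_matrix(
#'   matrix(c(10L, 990L, 20L, 980L), 2, 2,
#'          dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'   c(g1 = 2000, g2 = 1000), c(s1 = "A", s2 = "B")
#' )
#' rpkm(cm)$rpkm["g1", "s1"]  # 10 * 1e9 / (2000 * 1000) = 5000
#' @export
rpkm <- function(counts, total_mapped_reads = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  cm <- counts$counts
  if (is.null(total_mapped_reads)) {
    totals <- colSums(cm)
  } else {
    missing <- setdiff(colnames(cm), names(total_mapped_reads))
    if (length(missing)) {
      param_error(sprintf("no mapped-read total for sample %s", missing[1L]))
    }
    totals <- total_mapped_reads[colnames(cm)]
  }
  zero <- totals <= 0
  if (any(zero)) {
    param_error(sprintf("sample %s has zero mapped reads",
                        colnames(cm)[zero][1L]))
  }
  vals <- sweep(cm * 1e9 / counts$gene_lengths, 2L, totals, "/")
  structure(
    list(rpkm = vals, gene_lengths = counts$gene_lengths,
         groups = counts$groups, total_mapped_reads = totals),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (RPKM): %d genes x %d samples\n",
              nrow(x$rpkm), ncol(x$rpkm)))
  invisible(x)
}

#' Write an RPKM matrix as TSV (same layout as the count input)
#' @param x An `expression_matrix`.
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  tab <- data.frame(gene = rownames(x$rpkm), x$rpkm, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
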
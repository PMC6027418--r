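#' Construct a validated gene-level count matrix
#'
#' The container every downstream stage consumes: integer read counts for
#' genes by samples, per-gene transcript lengths in base pairs, and a group
#' label per sample. Group `"A"` is the recurrence arm, `"B"` the
#' non-recurrence arm of the comparison design.
#'
#' @param counts Integer matrix, genes in rows and samples in columns, with
#'   row and column names. Fractional or negative values are rejected, not
#'   rounded: no multi-mapping fractionation convention is assumed.
#' @param gene_lengths Named numeric vector of transcript lengths in bp,
#'   one per gene, each `>= 1`.
#' @param groups Named character vector mapping each sample id to `"A"` or
#'   `"B"`. Both groups must be non-empty.
#' @return An object of class `count_matrix` with elements `counts`,
#'   `gene_lengths` and `groups`.
#' @examples
#' cm <- count_matrix(
#'   counts = matrix(c(10L, 0L, 3L, 5L), 2, 2,
#'                   dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'   gene_lengths = c(g1 = 1000, g2 = 2000),
#'   groups = c(s1 = "A", s2 = "B")
#' )
#' @export
count_matrix <- function(counts, gene_lengths, groups) {
  if (!is.matrix(counts)) format_error("counts must be a matrix")
  gid <- rownames(counts)
  sid <- colnames(counts)
  if (is.null(gid) || is.null(sid)) {
    format_error("counts must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(gid)) {
    format_error(sprintf("duplicate gene id: %s", gid[duplicated(gid)][1L]))
  }
  if (anyDuplicated(sid)) {
    format_error(sprintf("duplicate sample id: %s", sid[duplicated(sid)][1L]))
  }
  if (any(is.na(counts))) format_error("counts contain missing values")
  if (any(counts < 0)) {
    bad <- gid[which(rowSums(counts < 0) > 0)][1L]
    format_error(sprintf("negative count for gene %s", bad))
  }
  if (any(counts != round(counts))) {
    bad <- gid[which(rowSums(counts != round(counts)) > 0)][1L]
    format_error(sprintf("non-integer count for gene %s", bad))
  }
  storage.mode(counts) <- "integer"

  missing_len <- setdiff(gid, names(gene_lengths))
  if (length(missing_len)) {
    format_error(sprintf("no length for gene: %s", missing_len[1L]))
  }
  gene_lengths <- gene_lengths[gid]
  if (any(is.na(gene_lengths)) || any(gene_lengths < 1) ||
      any(gene_lengths != round(gene_lengths))) {
    format_error("gene lengths must be integers >= 1 bp")
  }
  storage.mode(gene_lengths) <- "double"

  missing_grp <- setdiff(sid, names(groups))
  if (length(missing_grp)) {
    design_error(sprintf("no group label for sample: %s", missing_grp[1L]))
  }
  groups <- groups[sid]
  if (!all(groups %in% c("A", "B"))) {
    design_error("group labels must be 'A' (recurrence) or 'B' (non-recurrence)")
  }
  for (g in c("A", "B")) {
    if (!any(groups == g)) design_error(sprintf("group %s empty", g))
  }

  structure(
    list(counts = counts, gene_lengths = gene_lengths, groups = groups),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d genes x %d samples (A: %d recurrence, B: %d non-recurrence)\n",
    nrow(x$counts), ncol(x$counts),
    sum(x$groups == "A"), sum(x$groups == "B")
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix with lengths and group labels from disk
#'
#' @param path Tab-delimited count file: header row of sample ids, first
#'   column of gene ids.
#' @param lengths_path Two-column TSV mapping gene id to length in bp.
#' @param groups_path Two-column TSV mapping sample id to group (`A`/`B`).
#' @return A validated [count_matrix].
#' @export
read_count_matrix <- function(path, lengths_path, groups_path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) format_error("count file needs a gene column and >= 1 sample")
  gid <- tab[[1L]]
  if (anyDuplicated(gid)) {
    format_error(sprintf("duplicate gene id: %s", gid[duplicated(gid)][1L]))
  }
  num <- suppressWarnings(
    vapply(tab[-1L], function(col) as.numeric(col), numeric(nrow(tab)))
  )
  num <- matrix(num, nrow = nrow(tab),
                dimnames = list(gid, colnames(tab)[-1L]))
  if (any(is.na(num))) format_error("non-numeric entry in count file")

  len <- utils::read.delim(lengths_path, header = FALSE,
                           col.names = c("gene", "length_bp"))
  lengths <- stats::setNames(len$length_bp, len$gene)
  grp <- utils::read.delim(groups_path, header = FALSE,
                           col.names = c("sample", "group"),
                           colClasses = "character")
  groups <- stats::setNames(grp$group, grp$sample)

  count_matrix(num, lengths, groups)
}

#' Write a count matrix (and its side tables) to disk
#'
#' Inverse of [read_count_matrix()]; writing then re-reading yields an
#' identical structure.
#'
#' @param x A [count_matrix].
#' @param path,lengths_path,groups_path Output file paths.
#' @return Invisibly, `x`.
#' @export
write_count_matrix <- function(x, path, lengths_path, groups_path) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(gene = rownames(x$counts), x$counts, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(names(x$gene_lengths), unname(x$gene_lengths)),
    lengths_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  utils::write.table(
    data.frame(names(x$groups), unname(x$groups)),
    groups_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(x)
}
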
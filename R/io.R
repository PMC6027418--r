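#' Read a gene-set collection in GMT format
#'
#' One set per line: `name TAB description TAB member TAB member ...`.
#' Duplicate members within a set are collapsed; empty sets and duplicate
#' set names are rejected. Gene ids are opaque, case-sensitive strings —
#' no symbol/alias resolution is attempted.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: a named list of character vectors of
#'   member ids, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      format_error(sprintf("GMT line %d has fewer than 3 fields", i))
    }
    nm <- fields[[1L]]
    if (nm %in% names(sets)) {
      format_error(sprintf("duplicate set name: %s (line %d)", nm, i))
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      format_error(sprintf("empty gene set '%s' (line %d)", nm, i))
    }
    sets[[nm]] <- members
    descs[[nm]] <- fields[[2L]]
  }
  gene_set_collection(sets, descs)
}

#' Construct a gene-set collection in memory
#'
#' @param sets Named list of character vectors (member gene ids).
#' @param descriptions Optional named character vector of set descriptions.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!length(sets) || is.null(names(sets)) || anyDuplicated(names(sets))) {
    format_error("gene sets must be a non-empty, uniquely named list")
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0L)) format_error("gene sets must be non-empty")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions[names(sets)],
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param sets A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "descriptions") %||% stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descs[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}

#' Construct a validated qPCR cycle-threshold table
#'
#' Holds raw Ct values for genes by samples, a cohort label per sample
#' (`recurrence`, `non-recurrence`, or `calibrator` — the healthy-donor
#' livers whose average defines the 2^-ddCt baseline), and the designated
#' reference gene (beta-actin in the validation experiments this models).
#' Missing Ct values are kept as `NA` and excluded pairwise downstream.
#'
#' @param ct Numeric matrix of Ct values (PCR cycles), genes in rows,
#'   samples in columns, `NA` allowed.
#' @param groups Named character vector: sample id ->
#'   `recurrence` / `non-recurrence` / `calibrator`.
#' @param reference_gene Row name of the internal normalisation control.
#' @param ct_range Plausible Ct range; values outside are rejected.
#' @return A `ct_table` object. Samples lacking the reference gene's Ct are
#'   dropped with a warning.
#' @export
ct_table <- function(ct, groups, reference_gene, ct_range = c(0, 45)) {
  if (!is.matrix(ct) || is.null(rownames(ct)) || is.null(colnames(ct))) {
    format_error("ct must be a matrix with gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(ct))) format_error("duplicate gene id in Ct table")
  if (anyDuplicated(colnames(ct))) format_error("duplicate sample id in Ct table")
  if (!reference_gene %in% rownames(ct)) {
    format_error(sprintf("reference gene %s absent from Ct table", reference_gene))
  }
  out_of_range <- !is.na(ct) & (ct < ct_range[1] | ct > ct_range[2])
  if (any(out_of_range)) {
    idx <- which(out_of_range, arr.ind = TRUE)[1L, ]
    format_error(sprintf(
      "Ct out of range [%g, %g] for gene %s, sample %s",
      ct_range[1], ct_range[2], rownames(ct)[idx[1L]], colnames(ct)[idx[2L]]
    ))
  }
  missing_grp <- setdiff(colnames(ct), names(groups))
  if (length(missing_grp)) {
    design_error(sprintf("no group label for sample: %s", missing_grp[1L]))
  }
  groups <- groups[colnames(ct)]
  ok <- c("recurrence", "non-recurrence", "calibrator")
  if (!all(groups %in% ok)) {
    design_error(sprintf("Ct group labels must be one of: %s",
                         paste(ok, collapse = ", ")))
  }
  no_ref <- is.na(ct[reference_gene, ])
  if (any(no_ref)) {
    warning(sprintf("dropping %d sample(s) lacking reference-gene Ct: %s",
                    sum(no_ref), paste(colnames(ct)[no_ref], collapse = ", ")))
    ct <- ct[, !no_ref, drop = FALSE]
    groups <- groups[!no_ref]
  }
  if (!any(groups == "calibrator")) {
    design_error("Ct table has no calibrator samples")
  }
  structure(
    list(ct = ct, groups = groups, reference_gene = reference_gene,
         ct_range = ct_range),
    class = "ct_table"
  )
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf(
    "ct_table: %d genes x %d samples (%d recurrence, %d non-recurrence, %d calibrator); reference: %s\n",
    nrow(x$ct), ncol(x$ct),
    sum(x$groups == "recurrence"), sum(x$groups == "non-recurrence"),
    sum(x$groups == "calibrator"), x$reference_gene
  ))
  invisible(x)
}

#' Read a Ct table from CSV
#'
#' The header's first field declares the orientation. With first field
#' `sample`, rows are samples and columns are `sample,group,<gene>,...`.
#' With first field `gene`, rows are genes and columns are samples; a row
#' whose gene field is `group` carries the sample labels.
#'
#' @param path CSV path.
#' @param reference_gene Reference (normalisation) gene id.
#' @param ct_range Plausible Ct range (default 0-45 cycles).
#' @return A validated [ct_table].
#' @export
read_ct_table <- function(path, reference_gene, ct_range = c(0, 45)) {
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  orient <- colnames(tab)[1L]
  if (identical(orient, "sample")) {
    if (!"group" %in% colnames(tab)) design_error("Ct CSV lacks a group column")
    genes <- setdiff(colnames(tab), c("sample", "group"))
    ct <- matrix(vapply(tab[genes], as_ct_numeric, numeric(nrow(tab))),
                 nrow = nrow(tab), dimnames = list(tab$sample, genes))
    ct <- t(ct)
    groups <- stats::setNames(tab$group, tab$sample)
  } else if (identical(orient, "gene")) {
    grp_row <- which(tab$gene == "group")
    if (!length(grp_row)) design_error("gene-oriented Ct CSV lacks a 'group' row")
    samples <- colnames(tab)[-1L]
    groups <- stats::setNames(unlist(tab[grp_row[1L], -1L]), samples)
    body <- tab[-grp_row, , drop = FALSE]
    ct <- matrix(vapply(body[-1L], as_ct_numeric, numeric(nrow(body))),
                 nrow = nrow(body), dimnames = list(body$gene, samples))
  } else {
    format_error("Ct CSV header must start with 'sample' or 'gene'")
  }
  ct_table(ct, groups, reference_gene, ct_range)
}

as_ct_numeric <- function(x) {
  x[x %in% c("", "NA", "ND", "Undetermined")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  if (any(!is.na(x) & is.na(out))) format_error("non-numeric Ct value")
  out
}

#' Write a Ct table as sample-oriented CSV
#' @param x A [ct_table].
#' @param path Output path.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  tab <- data.frame(sample = colnames(x$ct), group = unname(x$groups),
                    t(x$ct), check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(x)
}

#' Read interaction-neighbour lists
#'
#' Two- or three-column TSV (`focal`, `neighbour`[, `score`]), the flat-file
#' form of an interaction-database export (confidence filtering is assumed
#' to have happened upstream). Several focal genes may share a file.
#'
#' @param path TSV path. A header row is detected and skipped if the third
#'   column is non-numeric.
#' @return Named list (by focal gene) of data frames with columns
#'   `neighbor` and `score` (`NA` when absent).
#' @export
read_neighbor_lists <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (!ncol(tab) %in% c(2L, 3L)) {
    format_error("neighbour file must have 2 or 3 tab-separated columns")
  }
  looks_header <- ncol(tab) == 3L &&
    is.na(suppressWarnings(as.numeric(tab[1L, 3L]))) ||
    identical(tolower(tab[1L, 1L]), "focal")
  if (looks_header) tab <- tab[-1L, , drop = FALSE]
  colnames(tab) <- c("focal", "neighbor", "score")[seq_len(ncol(tab))]
  if (ncol(tab) == 2L) tab$score <- NA_character_
  tab$score <- suppressWarnings(as.numeric(tab$score))
  if (any(!is.na(tab$score) & (tab$score < 0 | tab$score > 1))) {
    format_error("neighbour confidence scores must lie in [0, 1]")
  }
  split_tabs <- split(tab, tab$focal)
  lapply(split_tabs, function(d) {
    focal <- d$focal[1L]
    if (focal %in% d$neighbor) {
      format_error(sprintf("gene %s listed as its own neighbour", focal))
    }
    if (anyDuplicated(d$neighbor)) {
      format_error(sprintf("duplicate neighbour for focal gene %s", focal))
    }
    data.frame(neighbor = d$neighbor, score = d$score)
  })
}

#' Write a consensus DE result as a tab-delimited table
#'
#' Columns: `gene`, `direction`, `mean_log2_ratio`, `fold_change`,
#' `n_pairs_agreeing`, `consistent_flag`. Rows are every gene that received
#' at least one per-pair call, ordered by descending `|mean_log2_ratio|`
#' with ties broken lexicographically by gene id.
#'
#' @param result A `consensus_de` result (see [merge_and_filter()]).
#' @param path Output path.
#' @export
write_de_table <- function(result, path) {
  stopifnot(inherits(result, "consensus_de"))
  tab <- result$table
  tab <- tab[tab$direction != "null", , drop = FALSE]
  out <- data.frame(
    gene = tab$gene,
    direction = tab$direction,
    mean_log2_ratio = tab$mean_log2_ratio,
    fold_change = tab$fold_change,
    n_pairs_agreeing = tab$n_pairs_agreeing,
    consistent_flag = tab$direction %in% c("up", "down")
  )
  ord <- order(-abs(out$mean_log2_ratio), out$gene)
  out <- out[ord, , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
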
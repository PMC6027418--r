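#' Run the liver-graft expression pipeline end-to-end
#'
#' Orchestrates quantification, consensus differential expression, and
#' gene-set over-representation — plus, when the corresponding inputs are
#' configured, 2^-ddCt qPCR quantification with group comparison and
#' focal-gene correlation panels. Every stage output is written under the
#' configured output directory together with a machine-readable JSON run
#' report listing all parameters (defaults included), the gene and sample
#' counts surviving each stage, package version and wall time. Stage
#' outputs are deterministic: the same configuration yields byte-identical
#' files.
#'
#' @param config Either a path to a YAML configuration file or an
#'   equivalent named list. Recognised fields:
#' \describe{
#'   \item{counts, lengths, groups}{paths for [read_count_matrix()]
#'     (required).}
#'   \item{gene_sets}{GMT path for the enrichment stage (required).}
#'   \item{universe}{optional path, one gene id per line; defaults to the
#'     genes surviving the expression floor.}
#'   \item{ct_table, reference_gene, qpcr_targets}{optional qPCR stage:
#'     Ct CSV, reference gene id, target gene ids (default: every selected
#'     candidate present in the Ct table).}
#'   \item{neighbors, correlation_focal}{optional correlation stage:
#'     neighbour TSV and focal gene ids (default: every focal gene in the
#'     file).}
#'   \item{output_dir}{output directory (required; created if absent).}
#'   \item{params}{stage parameters: `per_pair_fold_threshold`,
#'     `pseudocount`, `expression_floor`, `mode`, `majority_fraction`,
#'     `ratio_scale`, `fold_cutoff`, `alpha`, `test`.}
#' }
#' @return Invisibly, a list with `report` (also written to
#'   `run_report.json`) and the in-memory stage `results`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) param_error("config must be a list or a YAML path")
  for (field in c("counts", "lengths", "groups", "gene_sets", "output_dir")) {
    if (is.null(config[[field]])) {
      param_error(sprintf("config field '%s' is required", field))
    }
  }
  for (field in c("counts", "lengths", "groups", "gene_sets",
                  "universe", "ct_table", "neighbors")) {
    p <- config[[field]]
    if (!is.null(p) && !file.exists(p)) {
      param_error(sprintf("config file for '%s' does not exist: %s", field, p))
    }
  }
  defaults <- list(
    per_pair_fold_threshold = 2, pseudocount = 0.1, expression_floor = 0.1,
    mode = "strict", majority_fraction = 0.9, ratio_scale = "log2",
    fold_cutoff = 2, alpha = 0.05, test = "mann_whitney"
  )
  params <- utils::modifyList(defaults, config$params %||% list())

  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- "read inputs"
  report <- list(package = "graftDE",
                 version = as.character(utils::packageVersion("graftDE")),
                 parameters = params, stages = list())
  res <- list()

  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline aborted at stage '%s': %s",
                   stage, conditionMessage(e)), call. = FALSE)
    })
  }

  cm <- run_stage("quantify (input validation)", {
    read_count_matrix(config$counts, config$lengths, config$groups)
  })
  report$stages$input <- list(
    n_genes = nrow(cm$counts), n_samples = ncol(cm$counts),
    n_group_A = sum(cm$groups == "A"), n_group_B = sum(cm$groups == "B")
  )

  expr <- run_stage("quantify", rpkm(cm))
  write_expression_matrix(expr, file.path(out_dir, "rpkm.tsv"))
  report$stages$quantify <- list(n_genes = nrow(expr$rpkm),
                                 n_samples = ncol(expr$rpkm))

  pw <- run_stage("pairwise comparison", {
    pairwise_lists(expr, params$per_pair_fold_threshold,
                   params$pseudocount, params$expression_floor)
  })
  report$stages$pairwise <- list(
    n_pairwise_lists = length(pw),
    n_genes_compared = length(attr(pw, "genes")),
    n_genes_floored = nrow(expr$rpkm) - length(attr(pw, "genes"))
  )

  cons <- run_stage("consensus merge", {
    merge_and_filter(pw, mode = params$mode,
                     majority_fraction = params$majority_fraction,
                     ratio_scale = params$ratio_scale)
  })
  write_de_table(cons, file.path(out_dir, "consensus_de.tsv"))
  dirs <- table(factor(cons$table$direction, c("up", "down", "removed", "null")))
  report$stages$consensus <- list(
    n_genes_in = length(attr(pw, "genes")),
    n_up = unname(dirs[["up"]]), n_down = unname(dirs[["down"]]),
    n_removed_inconsistent = unname(dirs[["removed"]]),
    n_uncalled = unname(dirs[["null"]])
  )

  cand <- run_stage("candidate selection",
                    select_candidates(cons, params$fold_cutoff))
  utils::write.table(cand, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$selection <- list(
    n_genes_in = report$stages$consensus$n_up + report$stages$consensus$n_down,
    n_selected = nrow(cand),
    n_up_candidates = sum(cand$direction == "up"),
    n_down_candidates = sum(cand$direction == "down")
  )

  enr <- run_stage("enrichment", {
    sets <- read_gmt(config$gene_sets)
    universe <- if (!is.null(config$universe)) {
      readLines(config$universe, warn = FALSE)
    } else {
      attr(pw, "genes")
    }
    enrich(cand$gene, sets, universe)
  })
  utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$enrichment <- list(
    n_query = nrow(cand), n_sets = nrow(enr),
    top_set = if (nrow(enr)) enr$set[1L] else NA_character_
  )
  res <- list(counts = cm, expression = expr, pairwise = pw,
              consensus = cons, candidates = cand, enrichment = enr)

  if (!is.null(config$ct_table)) {
    qp <- run_stage("qpcr", {
      if (is.null(config$reference_gene)) {
        param_error("reference_gene is required with a ct_table")
      }
      ctab <- read_ct_table(config$ct_table, config$reference_gene)
      targets <- config$qpcr_targets %||%
        intersect(cand$gene, rownames(ctab$ct))
      lapply(stats::setNames(targets, targets), function(g) {
        rel <- ddct(ctab, g)
        list(rel = rel, comparison = compare_groups(rel, params$test))
      })
    })
    qtab <- do.call(rbind, lapply(qp, function(q) {
      data.frame(gene = q$rel$gene, q$rel$samples, stringsAsFactors = FALSE)
    }))
    utils::write.table(qtab, file.path(out_dir, "qpcr_relative_levels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    qsum <- do.call(rbind, lapply(qp, function(q) {
      cc <- q$comparison
      data.frame(gene = cc$gene, test = cc$test, p_value = cc$p_value,
                 recurrence_median = cc$recurrence$median,
                 non_recurrence_median = cc$non_recurrence$median,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(qsum, file.path(out_dir, "qpcr_group_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$qpcr <- list(n_targets = length(qp),
                               n_significant = sum(qsum$p_value < params$alpha))
    res$qpcr <- qp
  }

  if (!is.null(config$neighbors)) {
    panels <- run_stage("correlation", {
      nbl <- read_neighbor_lists(config$neighbors)
      focal <- config$correlation_focal %||% names(nbl)
      lapply(stats::setNames(focal, focal), function(f) {
        correlation_panel(expr, f, nbl[[f]], alpha = params$alpha)
      })
    })
    ptab <- do.call(rbind, lapply(names(panels), function(f) {
      data.frame(focal = f, as.data.frame(panels[[f]]),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(ptab, file.path(out_dir, "correlation_panels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$correlation <- list(
      n_focal = length(panels),
      n_positive = sum(ptab$verdict == "positively correlated")
    )
    res$correlation = panels
  }

  report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(report = report, results = res))
}
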
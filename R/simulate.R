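#' Configuration for the RNA-seq count simulator
#'
#' Describes a two-group bulk RNA-seq experiment mirroring the liver-graft
#' design: `n_group_A` recurrence samples versus `n_group_B` non-recurrence
#' samples (6 vs 5 by default, i.e. eleven expression profiles), counts
#' drawn from a negative binomial whose per-gene mean is
#' `baseline_mean_counts` times a log-normal gene abundance factor, a
#' uniform library-size factor, and — for planted genes in group A — the
#' planted fold change. Dispersion 0 degenerates to Poisson. The seed fully
#' determines the output.
#'
#' @param n_genes Number of genes.
#' @param n_group_A,n_group_B Samples per group (defaults 6 and 5).
#' @param baseline_mean_counts Grand mean count before per-gene and
#'   per-library factors. Default 200.
#' @param dispersion Negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); 0 means Poisson. Default 0.05.
#' @param gene_length_range_bp Range transcript lengths are drawn from.
#'   Default 500-5000 bp.
#' @param planted_effects Named numeric vector: gene id -> true fold change
#'   of group A relative to group B (must be strictly positive). Genes are
#'   named `gene0001`... unless a name appears here, in which case that
#'   planted gene keeps its given id.
#' @param designated_set_name Name of the gene set that will hold the
#'   planted genes in [simulate_figure2_fixture()]-style collections.
#' @param library_size_jitter Range of the multiplicative per-sample
#'   library factor. Default 0.8-1.25.
#' @param gene_abundance_sdlog sdlog of the log-normal per-gene abundance
#'   factor, so RPKM spans realistic orders of magnitude. Default 1.
#' @param planted_abundance_range If non-NULL, planted genes draw their
#'   abundance factor uniformly from this range instead of the log-normal,
#'   keeping them clearly expressed (as genes detectable by a fold-change
#'   screen are). Default c(0.8, 2).
#' @param seed Integer seed; required.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes,
                              n_group_A = 6L,
                              n_group_B = 5L,
                              baseline_mean_counts = 200,
                              dispersion = 0.05,
                              gene_length_range_bp = c(500L, 5000L),
                              planted_effects = numeric(),
                              designated_set_name = "cell adhesion molecules",
                              library_size_jitter = c(0.8, 1.25),
                              gene_abundance_sdlog = 1,
                              planted_abundance_range = c(0.8, 2),
                              seed) {
  if (n_genes < 1 || n_group_A < 1 || n_group_B < 1) {
    param_error("n_genes and group sizes must be positive")
  }
  if (baseline_mean_counts <= 0) param_error("baseline_mean_counts must be > 0")
  if (dispersion < 0) param_error("dispersion must be >= 0")
  if (length(planted_effects) && is.null(names(planted_effects))) {
    param_error("planted_effects must be named by gene id")
  }
  if (any(planted_effects <= 0)) {
    param_error("planted fold changes must be strictly positive")
  }
  if (length(planted_effects) > n_genes) {
    param_error("more planted genes than genes in the universe")
  }
  if (missing(seed)) param_error("a seed is required for reproducibility")
  structure(
    list(n_genes = as.integer(n_genes),
         n_group_A = as.integer(n_group_A),
         n_group_B = as.integer(n_group_B),
         baseline_mean_counts = baseline_mean_counts,
         dispersion = dispersion,
         gene_length_range_bp = as.integer(gene_length_range_bp),
         planted_effects = planted_effects,
         designated_set_name = designated_set_name,
         library_size_jitter = library_size_jitter,
         gene_abundance_sdlog = gene_abundance_sdlog,
         planted_abundance_range = planted_abundance_range,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a two-group count matrix with planted fold changes
#'
#' @param config A [simulation_config()].
#' @return List with `counts` (a [count_matrix]) and `truth`, a data frame
#'   of `gene`, `true_fold` (A relative to B) and `direction`
#'   (`up`/`down`/`null`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n_g <- config$n_genes
    genes <- sprintf("gene%04d", seq_len(n_g))
    planted <- names(config$planted_effects)
    if (length(planted)) {
      if (length(unique(planted)) != length(planted)) {
        param_error("duplicate planted gene ids")
      }
      genes[seq_along(planted)] <- planted
    }
    n_a <- config$n_group_A
    n_b <- config$n_group_B
    samples <- c(sprintf("R%02d", seq_len(n_a)), sprintf("N%02d", seq_len(n_b)))
    groups <- stats::setNames(rep(c("A", "B"), c(n_a, n_b)), samples)

    lengths <- stats::setNames(
      sample(config$gene_length_range_bp[1]:config$gene_length_range_bp[2],
             n_g, replace = TRUE),
      genes
    )
    abundance <- stats::rlnorm(n_g, meanlog = 0,
                               sdlog = config$gene_abundance_sdlog)
    if (length(planted) && !is.null(config$planted_abundance_range)) {
      abundance[seq_along(planted)] <- stats::runif(
        length(planted),
        config$planted_abundance_range[1], config$planted_abundance_range[2]
      )
    }
    lib <- stats::runif(n_a + n_b, config$library_size_jitter[1],
                        config$library_size_jitter[2])

    fold <- stats::setNames(rep(1, n_g), genes)
    fold[planted] <- config$planted_effects[planted]

    mu <- config$baseline_mean_counts * abundance %o% lib
    mu[, seq_len(n_a)] <- mu[, seq_len(n_a)] * fold
    counts <- if (config$dispersion == 0) {
      stats::rpois(length(mu), lambda = mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    }
    counts <- matrix(as.integer(counts), nrow = n_g,
                     dimnames = list(genes, samples))

    truth <- data.frame(
      gene = genes,
      true_fold = unname(fold),
      direction = ifelse(fold > 1, "up", ifelse(fold < 1, "down", "null")),
      stringsAsFactors = FALSE
    )
    list(counts = count_matrix(counts, lengths, groups), truth = truth)
  })
}

#' Simulate the six-candidate fixture with the published direction pattern
#'
#' A ready-made experiment reproducing the qualitative pattern of the
#' cell-adhesion-molecule screen: four genes planted down in the
#' recurrence group (ITGA8, SELE, HFE, CDH26) and two planted up
#' (HLA-DQA2, CD274), embedded among null genes, with a gene-set
#' collection whose designated "cell adhesion molecules" set contains the
#' planted genes (the fold magnitudes are simulation choices, not
#' measured values). Dispersion is low so the planted pattern is
#' recoverable by the consensus procedure.
#'
#' @param seed Integer seed.
#' @param n_null Number of null background genes. Default 600.
#' @param dispersion NB overdispersion. Default 0.01.
#' @param baseline_mean_counts Default 1000.
#' @return List with `counts` (a [count_matrix]), `sets` (a
#'   `gene_set_collection` including the designated set), `truth`, and
#'   `config`.
#' @export
simulate_figure2_fixture <- function(seed, n_null = 600L, dispersion = 0.01,
                                     baseline_mean_counts = 1000) {
  planted <- c(
    ITGA8 = 1 / 4, SELE = 1 / 5, HFE = 1 / 4, CDH26 = 1 / 8,
    `HLA-DQA2` = 4, CD274 = 6
  )
  config <- simulation_config(
    n_genes = n_null + length(planted),
    baseline_mean_counts = baseline_mean_counts,
    dispersion = dispersion,
    planted_effects = planted,
    seed = seed
  )
  sim <- simulate_counts(config)
  genes <- sim$truth$gene
  nulls <- setdiff(genes, names(planted))
  decoys <- with_seed(seed + 1L, {
    list(
      cam_extra = sample(nulls, 4L),
      setA = sample(nulls, 25L),
      setB = sample(nulls, 40L)
    )
  })
  sets <- gene_set_collection(
    stats::setNames(
      list(
        c(names(planted), decoys$cam_extra),
        decoys$setA,
        decoys$setB
      ),
      c(config$designated_set_name, "xenobiotic metabolism (null)",
        "retinol metabolism (null)")
    ),
    descriptions = stats::setNames(
      c("designated set holding the planted candidates",
        "background set of null genes", "background set of null genes"),
      c(config$designated_set_name, "xenobiotic metabolism (null)",
        "retinol metabolism (null)")
    )
  )
  list(counts = sim$counts, sets = sets, truth = sim$truth, config = config)
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Constructs Ct values such that exact 2^-ddCt recovery holds at zero
#' noise: the reference gene is flat across samples, calibrator and
#' non-recurrence samples sit at a common target delta-Ct, and recurrence
#' samples are shifted by -log2(fold). Gaussian cycle noise of sd
#' `noise_sd` is then added independently to every Ct value.
#'
#' @param target_folds Named numeric vector: gene -> true fold change of
#'   the recurrence group relative to the calibrator baseline (strictly
#'   positive).
#' @param noise_sd Cycle noise standard deviation. Default 0.
#' @param seed Integer seed.
#' @param n_recurrence,n_non_recurrence,n_calibrator Samples per cohort
#'   (defaults 7, 7, 4 — the validation cohort sizes this emulates, plus a
#'   small donor panel).
#' @param reference_gene Reference gene id. Default `"ACTB"`.
#' @param base_ct Reference-gene Ct level. Default 20 cycles.
#' @param target_delta_ct Baseline target delta-Ct. Default 5 cycles.
#' @return A [ct_table] containing the targets and the reference gene.
#' @export
simulate_ct_table <- function(target_folds, noise_sd = 0, seed,
                              n_recurrence = 7L, n_non_recurrence = 7L,
                              n_calibrator = 4L,
                              reference_gene = "ACTB",
                              base_ct = 20, target_delta_ct = 5) {
  if (!length(target_folds) || is.null(names(target_folds))) {
    param_error("target_folds must be a named numeric vector")
  }
  if (any(target_folds <= 0)) {
    param_error("target fold changes must be strictly positive")
  }
  if (noise_sd < 0) param_error("noise_sd must be >= 0")
  with_seed(seed, {
    samples <- c(sprintf("R%02d", seq_len(n_recurrence)),
                 sprintf("N%02d", seq_len(n_non_recurrence)),
                 sprintf("D%02d", seq_len(n_calibrator)))
    groups <- stats::setNames(
      rep(c("recurrence", "non-recurrence", "calibrator"),
          c(n_recurrence, n_non_recurrence, n_calibrator)),
      samples
    )
    n_s <- length(samples)
    genes <- c(names(target_folds), reference_gene)
    ct <- matrix(NA_real_, length(genes), n_s,
                 dimnames = list(genes, samples))
    ct[reference_gene, ] <- base_ct
    for (g in names(target_folds)) {
      d_ct <- rep(target_delta_ct, n_s)
      rec <- groups == "recurrence"
      d_ct[rec] <- d_ct[rec] - log2(target_folds[[g]])
      ct[g, ] <- base_ct + d_ct
    }
    if (noise_sd > 0) {
      ct <- ct + matrix(stats::rnorm(length(ct), 0, noise_sd),
                        nrow(ct), ncol(ct))
    }
    ct_table(ct, groups, reference_gene)
  })
}
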
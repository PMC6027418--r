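# Independent brute-force oracles. These re-derive every quantity from
# first principles with naive loops / exhaustive enumeration and share no
# code with the package implementation.

# Consensus pairwise DE by explicit enumeration of every (A, B) pair.
oracle_consensus <- function(rpkm_mat, groups, threshold = 2,
                             pseudocount = 0.1) {
  a_ids <- names(groups)[groups == "A"]
  b_ids <- names(groups)[groups == "B"]
  genes <- rownames(rpkm_mat)
  res <- data.frame(gene = genes, direction = "null",
                    mean_log2_ratio = NA_real_, stringsAsFactors = FALSE)
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    lrs <- c(); ups <- 0L; downs <- 0L
    for (a in a_ids) {
      for (b in b_ids) {
        ratio <- (rpkm_mat[g, a] + pseudocount) / (rpkm_mat[g, b] + pseudocount)
        lr <- log2(ratio)
        lrs <- c(lrs, lr)
        if (lr >= log2(threshold)) ups <- ups + 1L
        if (lr <= -log2(threshold)) downs <- downs + 1L
      }
    }
    n_pairs <- length(a_ids) * length(b_ids)
    dir <- if (ups == n_pairs) "up"
           else if (downs == n_pairs) "down"
           else if (ups + downs > 0L) "removed"
           else "null"
    res$direction[gi] <- dir
    res$mean_log2_ratio[gi] <- sum(lrs) / n_pairs
  }
  res
}

# Hypergeometric upper tail by exhaustive enumeration of all size-n draws.
oracle_hypergeom_upper <- function(N, K, n, k) {
  if (n == 0L) return(if (k == 0L) 1 else 0)
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)   # set members are items 1..K
  mean(overlaps >= k)
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
oracle_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  u_stat <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  obs <- u_stat(seq_along(x))
  us <- apply(utils::combn(n, length(x)), 2L, u_stat)
  p <- 2 * min(mean(us <= obs), mean(us >= obs))
  min(p, 1)
}

# Two-sided Fisher exact p by enumerating all tables with the observed
# margins; tables no more probable than the observed one are summed
# (relative tolerance matching the conventional implementation).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  if (r1 == 0L || r1 == n || c1 == 0L || c1 == n) return(1)
  prob_a <- function(a) {
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  }
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, prob_a, numeric(1))
  p_obs <- prob_a(tab[1L, 1L])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
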
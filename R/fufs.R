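# Fu's FS neutrality statistic.
#
# Under the Ewens sampling distribution the number of distinct haplotypes K
# in a sample of n sequences with scaled mutation rate theta has
#   P(K = k) = |s(n, k)| theta^k / (theta (theta+1) ... (theta+n-1)),
# with |s(n, k)| unsigned Stirling numbers of the first kind. FS takes
# S' = P(K >= k_obs | theta = pi_hat) and reports ln(S' / (1 - S')); large
# negative values (an excess of haplotypes given the pairwise diversity)
# indicate population growth or selection.

log_stirling_row <- function(n) {
  # log |s(n, k)| for k = 0..n via the recursion
  # |s(n+1,k)| = n |s(n,k)| + |s(n,k-1)|, computed in log space
  logadd <- function(x, y) {
    m <- pmax(x, y)
    ifelse(is.infinite(m) & m < 0, -Inf, m + log1p(exp(-abs(x - y))))
  }
  row <- c(0, rep(-Inf, n))  # n = 0: s(0,0) = 1
  if (n == 0L) return(row)
  for (nn in 0:(n - 1L)) {
    new <- rep(-Inf, n + 1L)
    k <- 1:(nn + 1L)
    grow <- if (nn > 0) log(nn) + row[k + 1L] else rep(-Inf, length(k))
    new[k + 1L] <- logadd(grow, row[k])
    row <- new
  }
  row
}

#' Ewens probability of observing at least k haplotypes
#'
#' @param k observed number of distinct haplotypes.
#' @param n sample size.
#' @param theta scaled mutation rate (typically the sample's mean pairwise
#'   differences).
#' @return `P(K >= k | theta, n)` under the Ewens sampling distribution.
#' @export
ewens_p_at_least <- function(k, n, theta) {
  stopifnot(k >= 1, k <= n, theta > 0)
  ls <- log_stirling_row(n)
  logden <- sum(log(theta + 0:(n - 1L)))
  logp <- ls[(1:n) + 1L] + (1:n) * log(theta) - logden
  p <- exp(logp)
  sum(p[k:n]) / sum(p)
}

#' Fu's FS statistic with a coalescent null distribution
#'
#' Computes FS from the number of distinct haplotypes and the mean pairwise
#' differences of a sample, and its significance as the fraction of neutral
#' constant-size coalescent simulations (theta set to the observed pi)
#' whose simulated FS is less than or equal to the observed one.
#'
#' @param a an `hd_alignment`.
#' @param subset individual ids or deme label(s); `NULL` for everyone.
#' @param n_sim neutral simulations for the p-value (0 skips it).
#' @param seed integer seed.
#' @return list with `FS`, `p`, `k`, `pi`, `n`.
#' @export
fu_fs <- function(a, subset = NULL, n_sim = 10000, seed = 1) {
  ids <- a$ids
  if (!is.null(subset)) {
    ids <- if (all(subset %in% a$ids)) subset
           else a$ids[a$deme_of[a$ids] %in% subset]
  }
  n <- length(ids)
  if (n < 3L) stop("input error: need at least 3 sequences", call. = FALSE)
  sub <- subset_alignment(a, ids = ids)
  k <- length(collapse_haplotypes(sub)$hap_seqs)
  d <- pairwise_diff_matrix(sub$seqs)
  pi_hat <- mean(d[upper.tri(d)])
  if (pi_hat == 0) {
    if (k > 1L) stop("input error: several haplotypes but pi = 0", call. = FALSE)
    return(list(FS = NA_real_, p = NA_real_, k = k, pi = 0, n = n,
                note = "monomorphic sample: FS undefined"))
  }
  FS <- fs_from_summary(k, n, pi_hat)
  p <- NA_real_
  if (n_sim > 0) {
    rng <- local_rng(seed)
    sims <- vapply(seq_len(n_sim), function(b) {
      sim <- sim_genealogy_mutations(n, pi_hat)
      if (sim$pi == 0) return(Inf)  # no variation: never as extreme
      fs_from_summary(sim$k, n, sim$pi)
    }, 0)
    rng$restore()
    p <- mean(sims <= FS)
  }
  list(FS = FS, p = p, k = k, pi = pi_hat, n = n)
}

fs_from_summary <- function(k, n, pi_hat) {
  sp <- ewens_p_at_least(k, n, pi_hat)
  sp <- min(max(sp, 1e-300), 1 - 1e-15)
  log(sp / (1 - sp))
}

# Fast neutral constant-size coalescent summary (infinite sites): returns
# the number of distinct haplotypes and mean pairwise differences without
# materialising sequences.
sim_genealogy_mutations <- function(n, theta) {
  g <- sim_coalescent_tree(n, function(k) k * (k - 1) / 2 / theta)
  # mutations: Poisson(branch_length / 2) per branch (pair accumulates
  # Poisson(t) differences at rate 1/2 per lineage)
  nmut <- rpois(nrow(g$edges), g$edges[, "length"] / 2)
  # distinct haplotypes: tips separated by >= 1 mutation differ
  memb <- collapse_zero_branch(g, nmut)
  # pairwise differences via mutation counts on paths
  tip_sets <- g$tip_desc
  diffs <- 0
  for (e in seq_len(nrow(g$edges))) {
    if (nmut[e] == 0) next
    sz <- length(tip_sets[[g$edges[e, "child"]]])
    diffs <- diffs + nmut[e] * sz * (n - sz)
  }
  list(k = length(unique(memb)), pi = diffs / choose(n, 2))
}

collapse_zero_branch <- function(g, nmut) {
  # union tips connected through zero-mutation paths
  parent <- seq_len(g$n_nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in seq_len(nrow(g$edges))) {
    if (nmut[e] == 0) {
      a <- find(g$edges[e, "parent"]); b <- find(g$edges[e, "child"])
      parent[a] <- b
    }
  }
  vapply(seq_len(g$n_tips), function(i) as.integer(find(i)), 0L)
}
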
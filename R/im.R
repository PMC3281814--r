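# Two-deme isolation-with-migration coalescent sampler.
#
# Model: two demes of equal (unknown) mutation-scaled size theta = 2 N u
# split T time units ago (T in units of N generations) from an ancestral
# population of the same size, exchanging migrants symmetrically at scaled
# rate M = 2 N m. The sampler is a Metropolis-Hastings chain over the
# genealogy of the sampled sequences (topology, node times and explicit
# migration paths on branches) jointly with (theta, M, T), with uniform
# priors on [0, bound] for the three parameters and the structured
# coalescent as the genealogy prior. Sequence likelihoods use Felsenstein
# pruning under HKY with empirical base frequencies and a
# transition/transversion ratio estimated from the data.
#
# Units: with time in N-generation units a within-deme pair coalesces at
# rate 1, a lineage migrates at rate M/2, and a branch of duration t
# carries t * theta / 2 expected mutations per sequence. The mutation-scaled
# TMRCA reported in traces is root_time * theta / 2.

#' Configuration for the isolation-with-migration sampler
#'
#' Prior upper bounds are deliberately required: they materially affect
#' posterior modes and no silent default is appropriate.
#'
#' @param theta_max,M_max,T_max uniform prior upper bounds for theta
#'   (mutation-scaled size), M (2Nm) and T (split time, N-generation
#'   units).
#' @param steps MCMC steps per chain.
#' @param burnin_frac fraction of each chain discarded.
#' @param n_chains independent chains (dispersion diagnostic needs >= 2).
#' @param thin keep every `thin`-th state.
#' @param seed integer seed.
#' @param kappa HKY kappa; `NULL` estimates it from the data pair.
#' @return an `im_config` list.
#' @export
im_config <- function(theta_max, M_max, T_max, steps = 200000,
                      burnin_frac = 0.1, n_chains = 3, thin = 20, seed = 1,
                      kappa = NULL) {
  stopifnot(theta_max > 0, M_max >= 0, T_max > 0,
            burnin_frac >= 0, burnin_frac < 1)
  structure(list(theta_max = theta_max, M_max = M_max, T_max = T_max,
                 steps = steps, burnin_frac = burnin_frac,
                 n_chains = n_chains, thin = thin, seed = seed,
                 kappa = kappa), class = "im_config")
}

# --- data preparation -------------------------------------------------------

im_pattern_data <- function(seqs, kappa = NULL) {
  n <- nrow(seqs); L <- ncol(seqs)
  states <- matrix(match(seqs, VALID_BASES, nomatch = 0L), n, L)
  key <- apply(states, 2, paste, collapse = ",")
  ux <- !duplicated(key)
  pat <- states[, ux, drop = FALSE]
  w <- as.numeric(table(key)[key[ux]])
  freqs <- {
    s <- seqs[seqs %in% VALID_BASES]
    f <- tabulate(match(s, VALID_BASES), 4L) + 1
    setNames(f / sum(f), VALID_BASES)
  }
  if (is.null(kappa)) kappa <- estimate_kappa(seqs, freqs)
  hk <- hky_eigen(kappa, freqs)
  list(pat = pat, w = w, L = L, freqs = freqs, kappa = kappa, eig = hk)
}

estimate_kappa <- function(seqs, freqs) {
  n <- nrow(seqs)
  ts <- 0; tv <- 0
  is_ts <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    a <- seqs[i, ]; b <- seqs[j, ]
    use <- a %in% VALID_BASES & b %in% VALID_BASES & a != b
    ts <- ts + sum(is_ts(a[use], b[use]))
    tv <- tv + sum(use) - sum(is_ts(a[use], b[use]))
  }
  if (tv == 0 || ts == 0) return(4)
  R <- ts / tv
  piR <- freqs["A"] + freqs["G"]; piY <- freqs["C"] + freqs["T"]
  tv_w <- piR * piY
  ts_w <- freqs["A"] * freqs["G"] + freqs["C"] * freqs["T"]
  max(min(R * tv_w / ts_w, 100), 0.1)
}

# Eigendecomposition of the normalised HKY rate matrix (real and symmetric
# after the pi^(1/2) similarity transform).
hky_eigen <- function(kappa, freqs) {
  freqs <- freqs / sum(freqs)
  Q <- matrix(0, 4, 4)
  ts_pair <- matrix(c(1, 3, 3, 1, 2, 4, 4, 2), ncol = 2, byrow = TRUE)
  for (i in 1:4) for (j in 1:4) if (i != j) {
    k <- if (any(ts_pair[, 1] == i & ts_pair[, 2] == j)) kappa else 1
    Q[i, j] <- k * freqs[j]
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(freqs * diag(Q)))
  sp <- sqrt(freqs)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- diag(1 / sp) %*% e$vectors
  Vi <- t(e$vectors) %*% diag(sp)
  list(V = V, Vi = Vi, lambda = e$values, pi = as.numeric(freqs))
}

# HKY pruning log-likelihood of a genealogy state (R-facing wrapper).
im_loglik <- function(st, dat) {
  if (ncol(dat$pat) == 0L) return(0)
  root <- which(st$par == 0L)
  vs <- which(st$par != 0L)
  ord <- vs[order(st$time[st$par[vs]])]
  edges <- cbind(st$par[ord], ord)
  elen <- (st$time[st$par[ord]] - st$time[ord]) * st$theta / (2 * dat$L)
  hky_pruning_loglik(edges, elen, dat$pat, dat$w, dat$eig$V, dat$eig$Vi,
                     dat$eig$lambda, dat$eig$pi, length(st$par), root)
}

# --- genealogy prior --------------------------------------------------------

# Deme of each node at its own time (NA above T / for the root when
# children disagree there). Returns NULL if a node below T has children
# arriving in different demes (invalid state).
im_node_demes <- function(st) {
  n_nodes <- length(st$par)
  n <- (n_nodes + 1L) / 2L
  deme <- rep(NA_integer_, n_nodes)
  deme[seq_len(n)] <- st$tipdeme
  ord <- order(st$time)
  for (v in ord) {
    if (v <= n) next
    ch <- which(st$par == v)
    d_in <- vapply(ch, function(c) {
      d <- deme[c]
      if (is.na(d)) return(NA_integer_)
      if (length(st$mig[[c]]) %% 2L == 1L) 3L - d else d
    }, 0L)
    if (st$time[v] < st$T) {
      if (any(is.na(d_in)) || d_in[1] != d_in[2]) return(NULL)
      deme[v] <- d_in[1]
    } else {
      deme[v] <- NA_integer_
    }
  }
  deme
}

# Log-density of the genealogy (with migration paths) under the structured
# coalescent given (M, T); -Inf when invalid.
im_logprior <- function(st) {
  if (st$theta <= 0 || st$theta > st$theta_max) return(-Inf)
  if (st$M < 0 || st$M > st$M_max) return(-Inf)
  if (st$T <= 0 || st$T > st$T_max) return(-Inf)
  n_nodes <- length(st$par)
  n <- (n_nodes + 1L) / 2L
  # migration events must sit inside their edge and below T
  for (v in seq_len(n_nodes)) {
    mg <- st$mig[[v]]
    if (length(mg) == 0L) next
    if (st$par[v] == 0L) return(-Inf)
    if (any(mg >= st$T) || any(mg <= st$time[v]) ||
        any(mg >= st$time[st$par[v]])) return(-Inf)
    if (st$M == 0) return(-Inf)
  }
  deme <- im_node_demes(st)
  if (is.null(deme)) return(-Inf)
  # event sweep
  ev_t <- numeric(0); ev_k <- integer(0); ev_d <- integer(0)
  # coalescences
  internal <- which(seq_len(n_nodes) > n)
  ev_t <- st$time[internal]
  ev_k <- rep(1L, length(internal))             # 1 = coalescence
  ev_d <- ifelse(is.na(deme[internal]), 0L, deme[internal])
  # migrations (with direction from the path parity)
  for (v in seq_len(n_nodes)) {
    mg <- st$mig[[v]]
    if (length(mg) == 0L) next
    d <- deme[v]
    for (tm in mg) {
      ev_t <- c(ev_t, tm); ev_k <- c(ev_k, 2L); ev_d <- c(ev_d, d)
      d <- 3L - d
    }
  }
  ord <- order(ev_t)
  ev_t <- ev_t[ord]; ev_k <- ev_k[ord]; ev_d <- ev_d[ord]
  k <- c(sum(st$tipdeme == 1L), sum(st$tipdeme == 2L))
  lp <- 0
  t_cur <- 0
  Mh <- st$M / 2
  i <- 1L
  n_ev <- length(ev_t)
  pooled <- FALSE
  interval <- function(t0, t1, k, pooled) {
    if (t1 <= t0) return(0)
    if (!pooled)
      -(t1 - t0) * (k[1] * (k[1] - 1) / 2 + k[2] * (k[2] - 1) / 2 +
                      (k[1] + k[2]) * Mh)
    else -(t1 - t0) * sum(k) * (sum(k) - 1) / 2
  }
  while (i <= n_ev) {
    t_ev <- ev_t[i]
    if (!pooled && t_ev >= st$T) {
      lp <- lp + interval(t_cur, st$T, k, FALSE)
      t_cur <- st$T
      k <- c(sum(k), 0L)
      pooled <- TRUE
      next
    }
    lp <- lp + interval(t_cur, t_ev, k, pooled)
    t_cur <- t_ev
    if (ev_k[i] == 1L) {                         # coalescence
      if (!pooled) {
        d <- ev_d[i]
        if (d == 0L) return(-Inf)               # below T but deme-less
        if (k[d] < 2L) return(-Inf)
        k[d] <- k[d] - 1L
      } else {
        k[1] <- k[1] - 1L
      }
      # specific-pair coalescence rate is 1: log contribution 0
    } else {                                     # migration
      if (pooled) return(-Inf)
      d <- ev_d[i]
      if (k[d] < 1L) return(-Inf)
      k[d] <- k[d] - 1L; k[3L - d] <- k[3L - d] + 1L
      if (Mh <= 0) return(-Inf)
      lp <- lp + log(Mh)
    }
    i <- i + 1L
  }
  lp
}

# --- path proposal helpers --------------------------------------------------

# Simulate toggle times at rate M/2 on (0, len); when parity is 0 or 1 the
# simulation is retried until the toggle count matches that parity.
sim_toggles <- function(len, M, parity = NA, max_try = 200L) {
  if (M <= 0) {
    if (!is.na(parity) && parity == 1L) return(NULL)
    return(numeric(0))
  }
  for (b in seq_len(max_try)) {
    k <- rpois(1, M / 2 * len)
    if (is.na(parity) || k %% 2L == parity)
      return(sort(runif(k, 0, len)))
  }
  NULL
}

# log proposal density of a toggle path (count k over duration len),
# conditioned on parity when requested.
log_q_path <- function(k, len, M, parity = NA) {
  if (M <= 0) return(if (k == 0L) 0 else -Inf)
  base <- k * log(M / 2) - M / 2 * len
  if (is.na(parity)) return(base)
  pmatch_ <- if (parity == 0L) (1 + exp(-M * len)) / 2 else (1 - exp(-M * len)) / 2
  if (pmatch_ <= 0) return(-Inf)
  base - log(pmatch_)
}

# deme of the lineage starting at node v at time t (t within its edge)
lineage_deme_at <- function(st, deme, v, t) {
  d <- deme[v]
  if (is.na(d)) return(NA_integer_)
  k <- sum(st$mig[[v]] <= t)
  if (k %% 2L == 1L) 3L - d else d
}

# --- moves ------------------------------------------------------------------

subtree_nodes <- function(st, v) {
  out <- v
  frontier <- v
  while (length(frontier) > 0L) {
    ch <- which(st$par %in% frontier)
    out <- c(out, ch)
    frontier <- ch
  }
  out
}

move_param <- function(st, which_par, w) {
  val <- st[[which_par]]
  hi <- st[[paste0(which_par, "_max")]]
  prop <- val + runif(1, -w, w)
  # reflect into [0, hi]
  for (r in 1:10) {
    if (prop < 0) prop <- -prop
    else if (prop > hi) prop <- 2 * hi - prop
    else break
  }
  st[[which_par]] <- prop
  st
}

# Joint rescale of the genealogy timescale: all node times, migration
# times and T are multiplied by s while theta is divided by s, leaving
# every branch's expected mutation count (and hence the likelihood)
# unchanged. This traverses the theta-vs-time ridge that single-parameter
# moves cross slowly.
move_rescale <- function(st, a = 0.4) {
  s <- exp(runif(1, -a, a))
  n_nodes <- length(st$par)
  n <- (n_nodes + 1L) / 2L
  internal <- seq.int(n + 1L, n_nodes)
  st$time[internal] <- st$time[internal] * s
  K <- 0L
  for (v in seq_len(n_nodes)) {
    if (length(st$mig[[v]]) > 0L) {
      st$mig[[v]] <- st$mig[[v]] * s
      K <- K + length(st$mig[[v]])
    }
  }
  st$T <- st$T * s
  st$theta <- st$theta / s
  # Jacobian: n-1 node times + K migration times + T scale by s, theta by
  # 1/s
  list(st = st, lhr = (n - 1L + K) * log(s), lik_changes = FALSE)
}

move_node_time <- function(st, w_root = 1) {
  n_nodes <- length(st$par)
  n <- (n_nodes + 1L) / 2L
  v <- sample(seq.int(n + 1L, n_nodes), 1L)
  ch <- which(st$par == v)
  lb <- max(vapply(ch, function(c) {
    mx <- st$time[c]
    if (length(st$mig[[c]]) > 0L) mx <- max(mx, max(st$mig[[c]]))
    mx
  }, 0))
  if (st$par[v] != 0L) {
    ub <- st$time[st$par[v]]
    if (length(st$mig[[v]]) > 0L) ub <- min(ub, min(st$mig[[v]]))
    tprop <- runif(1, lb, ub)
    lhr <- 0
  } else {
    tprop <- st$time[v] + runif(1, -w_root, w_root)
    if (tprop < lb) tprop <- 2 * lb - tprop
    lhr <- 0
  }
  st$time[v] <- tprop
  list(st = st, lhr = lhr, lik_changes = TRUE)
}

move_resample_path <- function(st) {
  n_nodes <- length(st$par)
  deme <- im_node_demes(st)
  if (is.null(deme)) return(NULL)
  cand <- which(st$par != 0L & st$time < st$T)
  if (length(cand) == 0L) return(NULL)
  v <- if (length(cand) == 1L) cand else sample(cand, 1L)
  hi <- min(st$time[st$par[v]], st$T)
  len <- hi - st$time[v]
  if (len <= 0) return(NULL)
  start_d <- deme[v]
  constrained <- st$time[st$par[v]] < st$T
  old_k <- length(st$mig[[v]])
  parity <- if (constrained) old_k %% 2L else NA
  tg <- sim_toggles(len, st$M, parity)
  if (is.null(tg)) return(NULL)
  new_k <- length(tg)
  lhr <- log_q_path(old_k, len, st$M, parity) -
    log_q_path(new_k, len, st$M, parity)
  st$mig[[v]] <- st$time[v] + tg
  list(st = st, lhr = lhr, lik_changes = FALSE)
}

# Wilson-Balding: move the subtree rooted at v to a new attachment point.
move_wilson_balding <- function(st, lambda_root = 1) {
  n_nodes <- length(st$par)
  n <- (n_nodes + 1L) / 2L
  root <- which(st$par == 0L)
  v <- sample(setdiff(seq_len(n_nodes), root), 1L)
  p <- st$par[v]
  sib <- setdiff(which(st$par == p), v)
  g <- st$par[p]
  deme_old <- im_node_demes(st)
  if (is.null(deme_old)) return(NULL)

  # reverse-proposal ingredients at the old location
  old_tp <- st$time[p]
  old_vpath_len <- min(old_tp, st$T) - st$time[v]
  old_vk <- length(st$mig[[v]])
  old_constrained <- old_tp < st$T && st$time[v] < st$T
  rev_lq_v <- if (st$time[v] >= st$T) 0 else
    log_q_path(old_vk, old_vpath_len, st$M,
               if (old_constrained) old_vk %% 2L else NA)
  rev_extra <- 0
  if (g == 0L) {
    # reverse move is an above-root attach: sibling-edge path density
    # (unconstrained forward simulation) and exponential time density
    sp_len <- min(old_tp, st$T) - st$time[sib]
    sp_k <- length(st$mig[[sib]])
    if (sp_len > 0)
      rev_extra <- rev_extra + log_q_path(sp_k, sp_len, st$M, NA)
    lo_rev <- max(st$time[v], st$time[sib])
    rev_extra <- rev_extra + log(lambda_root) - lambda_root * (old_tp - lo_rev)
  }

  # detach: splice p out; merge sibling edge with p's edge, except when p
  # was the root, where the sibling becomes the root and its path is
  # deleted (accounted for in rev_extra above)
  det <- st
  det$mig[[sib]] <- if (g == 0L) numeric(0)
                    else sort(c(det$mig[[sib]], det$mig[[p]]))
  det$mig[[p]] <- numeric(0)
  det$par[sib] <- g
  det$par[v] <- 0L   # temporarily parentless
  det$par[p] <- -1L  # removed from tree
  new_root <- if (g == 0L) sib else root

  if (g != 0L) {
    # reverse time density: uniform on the merged sibling edge
    rev_len <- det$time[det$par[sib]] - max(det$time[v], det$time[sib])
    if (rev_len <= 0) return(NULL)
    rev_extra <- rev_extra - log(rev_len)
  }

  # feasible attachment targets on the detached tree
  excl <- c(subtree_nodes(det, v), p)
  targets <- setdiff(which(det$par > 0L), excl)
  targets <- targets[det$time[det$par[targets]] > det$time[v]]
  n_feas <- length(targets) + 1L  # + above-root attach

  pick <- sample.int(n_feas, 1L)
  fwd_lq <- 0
  new_st <- det
  if (pick <= length(targets)) {
    u <- targets[pick]
    lo <- max(det$time[v], det$time[u]); hi <- det$time[det$par[u]]
    tnew <- runif(1, lo, hi)
    fwd_lq <- fwd_lq - log(hi - lo)
    # splice p back in on edge u
    new_st$par[p] <- new_st$par[u]
    new_st$time[p] <- tnew
    new_st$par[u] <- p
    new_st$par[v] <- p
    mg <- new_st$mig[[u]]
    new_st$mig[[u]] <- mg[mg < tnew]
    new_st$mig[[p]] <- mg[mg >= tnew]
    # path for v's new edge
    if (new_st$time[v] < new_st$T) {
      plen <- min(tnew, new_st$T) - new_st$time[v]
      constrained <- tnew < new_st$T
      parity <- NA
      if (constrained) {
        d_target <- lineage_deme_at(det, deme_old, u, tnew)
        d_v <- deme_old[v]
        if (is.na(d_target) || is.na(d_v)) return(NULL)
        parity <- as.integer(d_target != d_v)
      }
      tg <- sim_toggles(plen, new_st$M, parity)
      if (is.null(tg)) return(NULL)
      new_st$mig[[v]] <- new_st$time[v] + tg
      fwd_lq <- fwd_lq + log_q_path(length(tg), plen, new_st$M, parity)
    } else new_st$mig[[v]] <- numeric(0)
  } else {
    # above-root attach: p becomes the new root
    lo <- max(det$time[v], det$time[new_root])
    tnew <- lo + rexp(1, lambda_root)
    fwd_lq <- fwd_lq + log(lambda_root) - lambda_root * (tnew - lo)
    new_st$par[p] <- 0L
    new_st$time[p] <- tnew
    new_st$par[new_root] <- p
    new_st$par[v] <- p
    # unconstrained path on the old-root edge
    rp_len <- min(tnew, new_st$T) - new_st$time[new_root]
    if (rp_len > 0) {
      tg <- sim_toggles(rp_len, new_st$M, NA)
      if (is.null(tg)) return(NULL)
      new_st$mig[[new_root]] <- new_st$time[new_root] + tg
      fwd_lq <- fwd_lq + log_q_path(length(tg), rp_len, new_st$M, NA)
    } else new_st$mig[[new_root]] <- numeric(0)
    # path for v's edge, endpoint free (new root has no constraint below T
    # only if tnew >= T; otherwise v must land in the same deme as the
    # old-root lineage at tnew)
    if (new_st$time[v] < new_st$T) {
      plen <- min(tnew, new_st$T) - new_st$time[v]
      parity <- NA
      if (tnew < new_st$T) {
        d_target <- {
          d0 <- deme_old[new_root]
          k <- length(new_st$mig[[new_root]])
          if (is.na(d0)) NA_integer_ else if (k %% 2L == 1L) 3L - d0 else d0
        }
        d_v <- deme_old[v]
        if (is.na(d_target) || is.na(d_v)) return(NULL)
        parity <- as.integer(d_target != d_v)
      }
      tg <- sim_toggles(plen, new_st$M, parity)
      if (is.null(tg)) return(NULL)
      new_st$mig[[v]] <- new_st$time[v] + tg
      fwd_lq <- fwd_lq + log_q_path(length(tg), plen, new_st$M, parity)
    } else new_st$mig[[v]] <- numeric(0)
  }
  list(st = new_st, lhr = rev_lq_v + rev_extra - fwd_lq, lik_changes = TRUE)
}

# --- sampler ----------------------------------------------------------------

im_init_state <- function(tipdeme, cfg) {
  n <- length(tipdeme)
  T0 <- cfg$T_max / 2
  # valid starting genealogy: within-deme coalescence before T0, pooled
  # afterwards (no migration events)
  tb <- new_tree_builder(n)
  active <- seq_len(n); deme <- tipdeme; t <- 0
  while (length(active) > 1L) {
    k1 <- sum(deme == 1L); k2 <- sum(deme == 2L)
    if (t < T0) {
      rate <- k1 * (k1 - 1) / 2 + k2 * (k2 - 1) / 2
      if (rate == 0) { t <- T0; deme <- rep(1L, length(active)); next }
      w <- rexp(1, rate)
      if (t + w >= T0) { t <- T0; deme <- rep(1L, length(active)); next }
      t <- t + w
      d <- sample(1:2, 1, prob = c(k1 * (k1 - 1), k2 * (k2 - 1)))
      ix <- which(deme == d)
    } else {
      k <- length(active)
      t <- t + rexp(1, k * (k - 1) / 2)
      ix <- seq_along(active)
      d <- 1L
    }
    pair <- ix[sample.int(length(ix), 2L)]
    pnode <- tb_coalesce(tb, active[pair[1]], active[pair[2]], t)
    keep <- setdiff(seq_along(active), pair)
    active <- c(active[keep], pnode); deme <- c(deme[keep], d)
  }
  tr <- tb_finish(tb)
  par <- integer(tr$n_nodes)
  for (e in seq_len(nrow(tr$edges)))
    par[tr$edges[e, "child"]] <- tr$edges[e, "parent"]
  list(par = par, time = tr$times, mig = rep(list(numeric(0)), tr$n_nodes),
       tipdeme = tipdeme, theta = cfg$theta_max / 4, M = cfg$M_max / 4,
       T = T0, theta_max = cfg$theta_max, M_max = cfg$M_max,
       T_max = cfg$T_max)
}

im_run_chain <- function(dat, tipdeme, cfg, chain_seed) {
  rng <- local_rng(chain_seed)
  on.exit(rng$restore())
  st <- im_init_state(tipdeme, cfg)
  lp <- im_logprior(st)
  stopifnot(is.finite(lp))
  ll <- im_loglik(st, dat)
  w_theta <- max(st$theta_max / 6, 1e-3)
  w_M <- max(st$M_max / 6, 1e-3)
  w_T <- max(st$T_max / 6, 1e-3)
  keep <- floor(cfg$steps / cfg$thin)
  trace <- matrix(NA_real_, keep, 6,
                  dimnames = list(NULL, c("theta", "M", "T", "root_time",
                                          "tmrca", "tau_split")))
  acc <- c(theta = 0, M = 0, T = 0, time = 0, path = 0, wb = 0, rescale = 0)
  tries <- acc
  probs <- c(theta = 0.12, M = 0.08, T = 0.14, time = 0.26, path = 0.10,
             wb = 0.18, rescale = 0.12)
  kinds <- names(probs)
  ki <- sample(kinds, cfg$steps, replace = TRUE, prob = probs)
  row <- 0L
  for (it in seq_len(cfg$steps)) {
    kind <- ki[it]
    tries[kind] <- tries[kind] + 1
    prop <- switch(kind,
      theta = list(st = move_param(st, "theta", w_theta), lhr = 0,
                   lik_changes = TRUE, prior_changes = FALSE),
      M = list(st = move_param(st, "M", w_M), lhr = 0, lik_changes = FALSE,
               prior_changes = TRUE),
      T = list(st = move_param(st, "T", w_T), lhr = 0, lik_changes = FALSE,
               prior_changes = TRUE),
      time = move_node_time(st),
      path = move_resample_path(st),
      wb = move_wilson_balding(st),
      rescale = move_rescale(st))
    if (!is.null(prop)) {
      # genealogy prior is theta-free and move_param reflects into the
      # prior support, so theta moves only change the likelihood
      lp_new <- if (kind == "theta") lp else im_logprior(prop$st)
      if (is.finite(lp_new)) {
        ll_new <- if (prop$lik_changes) im_loglik(prop$st, dat) else ll
        logr <- (lp_new + ll_new) - (lp + ll) + prop$lhr
        if (log(runif(1)) < logr) {
          st <- prop$st; lp <- lp_new; ll <- ll_new
          acc[kind] <- acc[kind] + 1
        }
      }
    }
    if (it %% cfg$thin == 0L) {
      row <- row + 1L
      rt <- max(st$time)
      trace[row, ] <- c(st$theta, st$M, st$T, rt, rt * st$theta / 2,
                        st$T * st$theta / 2)
    }
  }
  burn <- floor(nrow(trace) * cfg$burnin_frac)
  list(trace = as.data.frame(trace[(burn + 1):nrow(trace), , drop = FALSE]),
       acceptance = ifelse(tries > 0, acc / tries, NA))
}

posterior_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 10L || sd(x) == 0) return(mean(x))
  iqr <- stats::IQR(x)
  bw <- if (iqr > 0) 2 * iqr / length(x)^(1 / 3) else diff(range(x)) / 30
  if (bw <= 0) return(mean(x))
  br <- seq(min(x) - bw, max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  h$mids[which.max(h$counts)]
}

split_rhat <- function(chains) {
  # simple potential-scale-reduction on the per-chain vectors
  m <- length(chains)
  if (m < 2L) return(NA_real_)
  n <- min(lengths(chains))
  xs <- vapply(chains, function(x) x[seq_len(n)], numeric(n))
  W <- mean(apply(xs, 2, stats::var))
  B <- n * stats::var(colMeans(xs))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Run the two-deme isolation-with-migration sampler
#'
#' Samples genealogies (topology, node times, explicit migration paths)
#' jointly with theta, M and T for the individuals of two demes, under
#' uniform priors and an HKY substitution model, and returns traces,
#' posterior modes and a between-chain mixing diagnostic (split R-hat over
#' the chains; the result is flagged when any parameter exceeds the
#' threshold).
#'
#' @param a an `hd_alignment`.
#' @param deme_pair character vector of two deme labels (or two character
#'   vectors of deme labels to pool per side).
#' @param cfg an [im_config()].
#' @param rhat_threshold flag threshold for the dispersion diagnostic.
#' @return an `im_posterior` list: `traces` (per chain), `modes`, `rhat`,
#'   `flagged`, `acceptance`, `config`, `kappa`, `n`.
#' @export
run_mdiv <- function(a, deme_pair, cfg, rhat_threshold = 1.2) {
  side <- function(x) a$ids[a$deme_of[a$ids] %in% x]
  ids1 <- side(deme_pair[[1]]); ids2 <- side(deme_pair[[2]])
  if (length(ids1) == 0L || length(ids2) == 0L)
    stop("both demes must be sampled", call. = FALSE)
  ids <- c(ids1, ids2)
  seqs <- a$seqs[ids, , drop = FALSE]
  dat <- im_pattern_data(seqs, kappa = cfg$kappa)
  tipdeme <- c(rep(1L, length(ids1)), rep(2L, length(ids2)))
  chains <- lapply(seq_len(cfg$n_chains), function(ci)
    im_run_chain(dat, tipdeme, cfg, chain_seed = cfg$seed * 1000 + ci))
  traces <- lapply(chains, `[[`, "trace")
  pooled <- do.call(rbind, traces)
  modes <- vapply(c("theta", "M", "T", "tmrca", "tau_split"), function(p)
    posterior_mode(pooled[[p]]), 0)
  # the mutation-scaled quantities tau_split = T theta / 2 and TMRCA are
  # what the sequences identify sharply; the split time in N-generation
  # units is best estimated from them rather than from the theta-smeared
  # marginal of T itself
  modes["T"] <- 2 * modes[["tau_split"]] / modes[["theta"]]
  rhat <- vapply(c("theta", "M", "T"), function(p)
    split_rhat(lapply(traces, `[[`, p)), 0)
  flagged <- any(rhat > rhat_threshold, na.rm = TRUE)
  no_variation <- ncol(dat$pat) == 0L ||
    all(apply(dat$pat, 2, function(col) length(unique(col[col > 0])) <= 1L))
  structure(list(traces = traces, modes = modes, rhat = rhat,
                 flagged = flagged || no_variation,
                 flag_reason = if (no_variation) "no sequence variation"
                               else if (flagged) "chains not mixed" else NULL,
                 acceptance = lapply(chains, `[[`, "acceptance"),
                 config = cfg, kappa = dat$kappa,
                 n = c(length(ids1), length(ids2))),
            class = "im_posterior")
}

#' @export
print.im_posterior <- function(x, ...) {
  cat(sprintf("IM posterior (%d + %d sequences, kappa = %.2f)\n",
              x$n[1], x$n[2], x$kappa))
  cat(sprintf("  modes: theta = %.3f, M = %.3f, T = %.3f, TMRCA = %.3f\n",
              x$modes["theta"], x$modes["M"], x$modes["T"],
              x$modes["tmrca"]))
  cat(sprintf("  rhat: %s%s\n",
              paste(sprintf("%s=%.2f", names(x$rhat), x$rhat), collapse = ", "),
              if (x$flagged) paste0("  [FLAGGED: ", x$flag_reason, "]") else ""))
  invisible(x)
}

#' Natural-unit summary of an IM posterior
#'
#' Converts the posterior modes to effective female population sizes and
#' years over a range of generation times: N_ef = theta / (2 u g) with u
#' the per-sequence per-year mutation rate and g the generation time in
#' years. Calendar-time conversions of the mutation-scaled quantities
#' depend on the yearly rate only: T_years = T theta / (2 u) and
#' TMRCA_years = TMRCA / u for every g; the table reports them per
#' generation time to make that explicit. The TMRCA/T ratio (root age over
#' split time, same time units) is the past-isolation diagnostic: values
#' well above 1 indicate coalescence far predating the divergence under
#' migration, values near or below 1 a recent split.
#'
#' @param p an `im_posterior`.
#' @param rm a [rate_model()] (its `generation_years` is ignored here).
#' @param generations vector of generation times (years) to tabulate.
#' @return list with `table` (per generation time) and `tmrca_over_T`.
#' @export
summarize_im <- function(p, rm = rate_model(), generations = c(1, 10)) {
  u <- rm$u_seq
  th <- p$modes["theta"]; Tm <- p$modes["T"]; tm <- p$modes["tmrca"]
  tab <- data.frame(
    generation_years = generations,
    N_ef = th / (2 * u * generations),
    T_years = rep(Tm * th / (2 * u), length(generations)),
    TMRCA_years = rep(tm / u, length(generations)))
  ratio <- unname((tm * 2 / th) / Tm)  # root time over split time
  out <- list(table = tab, tmrca_over_T = ratio, flagged = p$flagged,
              flag_reason = p$flag_reason)
  out
}

#' Write IM traces and posterior summary as TSV
#' @param p an `im_posterior`
#' @param dir output directory
#' @param prefix file prefix
#' @param rm rate model for the summary conversion
#' @return invisibly, the paths
#' @export
write_im_results <- function(p, dir, prefix = "im", rm = rate_model()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ci in seq_along(p$traces)) {
    f <- file.path(dir, sprintf("%s_trace_chain%d.tsv", prefix, ci))
    write.table(p$traces[[ci]], f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, f)
  }
  s <- summarize_im(p, rm)
  f <- file.path(dir, paste0(prefix, "_summary.tsv"))
  tab <- s$table
  tab$tmrca_over_T <- s$tmrca_over_T
  tab$flagged <- s$flagged
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, f))
}
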
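# Mismatch distributions and expansion-model fitting.
#
# Stationary baseline: for a stationary population with mutation-scaled
# size theta, the number of differences between two sequences is geometric,
#   Fhat_j(theta) = theta^j / (1 + theta)^(j+1).
#
# Sudden demographic expansion (theta0 -> theta1 at tau mutational time
# units before present): integrating the pairwise coalescent over the two
# epochs gives
#   F_j = Fhat_j(theta1) * P(Pois(a1 tau) > j)
#       + exp(-tau/theta1) * sum_i dpois(i, tau) Fhat_{j-i}(theta0),
# with a1 = (theta1 + 1)/theta1: either the pair coalesces in the new
# regime, or it survives past the expansion (prob exp(-tau/theta1)),
# accumulating Poisson(tau) mutations on the way plus a geometric(theta0)
# contribution from the ancestral epoch.
#
# Spatial expansion (infinite-island, deme size theta, scaled migration
# M = 2Nm): two lineages sampled in one deme coalesce there (rate 1/theta)
# or scatter (per-lineage rate M/(2 theta)); scattered lineages cannot meet
# again until the expansion time tau, when all lineages fall into the
# single ancestral deme of size theta.

fhat_stationary <- function(j, theta) {
  if (theta <= 0) return(as.numeric(j == 0))
  exp(j * log(theta) - (j + 1) * log1p(theta))
}

#' Expected mismatch distribution under sudden demographic expansion
#' @param jmax largest difference count to evaluate (vector is 0..jmax).
#' @param tau expansion time in mutational units.
#' @param theta0,theta1 mutation-scaled sizes before/after the expansion.
#' @return numeric vector of probabilities for 0..jmax differences.
#' @export
expected_mismatch_demographic <- function(jmax, tau, theta0, theta1) {
  j <- 0:jmax
  a1 <- (theta1 + 1) / theta1
  surv <- exp(-tau / theta1)
  term1 <- fhat_stationary(j, theta1) * stats::ppois(j, a1 * tau,
                                                     lower.tail = FALSE)
  fh0 <- fhat_stationary(j, theta0)
  pois <- stats::dpois(j, tau)
  term2 <- surv * vapply(j, function(jj) {
    sum(pois[1:(jj + 1)] * fh0[(jj + 1):1])
  }, 0)
  term1 + term2
}

#' Expected mismatch distribution under spatial (infinite-island) expansion
#' @param jmax largest difference count to evaluate.
#' @param tau expansion time in mutational units.
#' @param theta mutation-scaled deme size (theta0 = theta1 = theta).
#' @param M scaled migration rate 2Nm with the infinite pool.
#' @return numeric vector of probabilities for 0..jmax differences.
#' @export
expected_mismatch_spatial <- function(jmax, tau, theta, M) {
  j <- 0:jmax
  b <- (1 + M) / theta + 1
  # coalescence inside the deme before tau
  A <- (1 / theta) * exp(-(j + 1) * log(b) + stats::pgamma(tau, shape = j + 1,
                                                           rate = b, log.p = TRUE))
  esc <- exp(-(1 + M) * tau / theta)
  w <- M / (1 + M) * (1 - esc) + esc
  fh <- fhat_stationary(j, theta)
  pois <- stats::dpois(j, tau)
  B <- vapply(j, function(jj) sum(pois[1:(jj + 1)] * fh[(jj + 1):1]), 0)
  A + w * B
}

#' Observed mismatch distribution
#'
#' Histogram of pairwise site differences over all pairs in a subset of
#' individuals, normalised to probabilities, plus its mean (identical to
#' the deme's mean pairwise differences pi).
#'
#' @param a an `hd_alignment`.
#' @param subset individual ids, a deme label, or `NULL` for everyone.
#' @return list with `probs` (named vector over 0..max), `mean`, `n`.
#' @export
observed_mismatch <- function(a, subset = NULL) {
  ids <- a$ids
  if (!is.null(subset)) {
    ids <- if (all(subset %in% a$ids)) subset
           else a$ids[a$deme_of[a$ids] %in% subset]
  }
  n <- length(ids)
  if (n < 2L) stop("input error: need at least 2 individuals", call. = FALSE)
  d <- pairwise_diff_matrix(a$seqs[ids, , drop = FALSE])
  dv <- d[upper.tri(d)]
  probs <- tabulate(dv + 1L, nbins = max(dv) + 1L) / length(dv)
  names(probs) <- 0:max(dv)
  list(probs = probs, mean = mean(dv), n = n)
}

ssd_mismatch <- function(obs_probs, exp_probs) sum((obs_probs - exp_probs)^2)

fit_expansion_curve <- function(obs_probs, model = c("demographic", "spatial"),
                                theta_cap = 9999, coarse = FALSE) {
  model <- match.arg(model)
  jmax <- length(obs_probs) - 1L
  obs_mean <- sum((0:jmax) * obs_probs)
  tr <- function(x) pmin(exp(x), theta_cap)
  objective <- function(par) {
    tau <- min(exp(par[1]), 500)
    e <- if (model == "demographic")
      expected_mismatch_demographic(jmax, tau, tr(par[2]), tr(par[3]))
    else
      expected_mismatch_spatial(jmax, tau, tr(par[2]), tr(par[3]))
    ssd_mismatch(obs_probs, e)
  }
  m0 <- max(obs_mean, 0.1)
  if (coarse) {
    # reduced start grid for bootstrap refits
    tau_starts <- log(m0)
    second <- if (model == "demographic") log(c(0.001, 0.5)) else log(c(0.1, m0))
    third <- if (model == "demographic") log(c(m0, 100)) else log(c(0.5, 100))
  } else {
    tau_starts <- log(c(0.25 * m0, m0, 2 * m0))
    second <- if (model == "demographic") log(c(0.001, 0.5)) else log(c(0.1, m0))
    third <- if (model == "demographic") log(c(m0, 20 * m0, 500)) else log(c(0.2, 5, 500))
  }
  best <- NULL
  for (t0 in tau_starts) for (s0 in second) for (u0 in third) {
    fit <- tryCatch(
      optim(c(t0, s0, u0), objective, method = "Nelder-Mead",
            control = list(maxit = 800, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("mismatch fit failed to converge", call. = FALSE)
  par <- best$par
  out <- list(model = model, tau = min(exp(par[1]), 500),
              ssd = best$value, converged = best$convergence == 0)
  if (model == "demographic") {
    out$theta0 <- tr(par[2]); out$theta1 <- tr(par[3])
  } else {
    out$theta <- tr(par[2]); out$M <- tr(par[3])
  }
  out
}

bootstrap_p_ssd <- function(fit, obs_probs, n, L, n_boot, seed,
                            model) {
  if (n_boot <= 0) return(NA_real_)
  rng <- local_rng(seed)
  on.exit(rng$restore())
  cnt <- 0L; used <- 0L
  for (b in seq_len(n_boot)) {
    sim <- if (model == "demographic")
      simulate_coalescent(scenario = "sudden_expansion", n = n, L = L,
                          tau = fit$tau, theta0 = fit$theta0,
                          theta1 = fit$theta1, mutation = "infinite_sites",
                          seed = NULL)
    else
      simulate_coalescent(scenario = "spatial_expansion", n = n, L = L,
                          tau = fit$tau, theta = fit$theta, M = fit$M,
                          mutation = "infinite_sites", seed = NULL)
    om <- observed_mismatch(sim$alignment)
    refit <- tryCatch(fit_expansion_curve(om$probs, model = model,
                                          coarse = TRUE),
                      error = function(e) NULL)
    if (is.null(refit)) next
    used <- used + 1L
    if (refit$ssd >= fit$ssd) cnt <- cnt + 1L
  }
  if (used == 0L) return(NA_real_)
  cnt / used
}

#' Fit the sudden demographic expansion model to a mismatch distribution
#'
#' Least-squares fit of (tau, theta0, theta1) to the observed mismatch by
#' multi-start Nelder-Mead on log parameters (theta capped at 9999), with
#' goodness of fit from a parametric bootstrap: samples of size `n` are
#' simulated by the package's coalescent under the fitted expansion,
#' refitted, and P_SSD is the fraction with SSD at least the observed fit's
#' SSD.
#'
#' @param obs observed mismatch probabilities over 0..max (from
#'   [observed_mismatch()]`$probs`).
#' @param n sample size behind the observed distribution.
#' @param L alignment length (used by the bootstrap simulations).
#' @param n_boot parametric bootstrap replicates (0 skips P_SSD).
#' @param seed integer seed for the bootstrap.
#' @return an `hd_mismatch_fit` list: `model`, `obs`, `obs_mean`, `tau`,
#'   `theta0`, `theta1`, `ssd`, `p_ssd`, `converged`.
#' @export
fit_demographic <- function(obs, n, L = 1000, n_boot = 1000, seed = 1) {
  fit <- fit_expansion_curve(obs, "demographic")
  fit$obs <- obs
  fit$obs_mean <- sum((seq_along(obs) - 1) * obs)
  fit$n <- n
  fit$p_ssd <- bootstrap_p_ssd(fit, obs, n, L, n_boot, seed, "demographic")
  class(fit) <- "hd_mismatch_fit"
  fit
}

#' Fit the spatial (infinite-island) expansion model
#'
#' Same contract as [fit_demographic()], for parameters (tau, theta, M).
#'
#' @inheritParams fit_demographic
#' @return an `hd_mismatch_fit` with `tau`, `theta`, `M`.
#' @export
fit_spatial <- function(obs, n, L = 1000, n_boot = 1000, seed = 1) {
  fit <- fit_expansion_curve(obs, "spatial")
  fit$obs <- obs
  fit$obs_mean <- sum((seq_along(obs) - 1) * obs)
  fit$n <- n
  fit$p_ssd <- bootstrap_p_ssd(fit, obs, n, L, n_boot, seed, "spatial")
  class(fit) <- "hd_mismatch_fit"
  fit
}

#' @export
print.hd_mismatch_fit <- function(x, ...) {
  cat(sprintf("Mismatch fit (%s expansion): tau = %.3f", x$model, x$tau))
  if (x$model == "demographic")
    cat(sprintf(", theta0 = %.3f, theta1 = %.3f", x$theta0, x$theta1))
  else
    cat(sprintf(", theta = %.3f, M = %.3f", x$theta, x$M))
  cat(sprintf("\n  obs mean = %.3f, SSD = %.3g, P_SSD = %s\n",
              x$obs_mean, x$ssd,
              if (is.na(x$p_ssd)) "NA" else sprintf("%.3f", x$p_ssd)))
  invisible(x)
}

#' Mutation-rate model for natural-unit conversions
#'
#' The package's default follows a divergence rate of 2% per million years
#' over an effective sequence length of about 1 kb, i.e. a per-sequence
#' mutation rate u_seq = 2e-5 per year (so 2u = 4e-5 per year for a pair),
#' and a configurable generation time in years.
#'
#' @param u_seq mutations per sequence per year.
#' @param generation_years generation time in years.
#' @return a `rate_model` list.
#' @export
rate_model <- function(u_seq = 2e-5, generation_years = 1) {
  if (u_seq <= 0) stop("u_seq must be positive", call. = FALSE)
  structure(list(u_seq = u_seq, generation_years = generation_years),
            class = "rate_model")
}

#' Convert mutation-scaled expansion parameters to natural units
#'
#' T = tau / (2 u) generations (times generation length in years),
#' N = theta / (2 u) females, and for the spatial model the immigration
#' rate m = M / (2 N).
#'
#' @param fit an `hd_mismatch_fit`.
#' @param rm a [rate_model()].
#' @return list of conversions: `T_years` plus `N0`, `N1` (demographic) or
#'   `N`, `m_immigration` (spatial).
#' @export
to_natural_units <- function(fit, rm = rate_model()) {
  two_u <- 2 * rm$u_seq
  out <- list(T_years = fit$tau / two_u * rm$generation_years)
  if (fit$model == "demographic") {
    out$N0 <- fit$theta0 / two_u
    out$N1 <- fit$theta1 / two_u
  } else {
    out$N <- fit$theta / two_u
    out$m_immigration <- if (fit$theta > 0) fit$M / (2 * fit$theta / two_u)
                         else NA_real_
  }
  out
}

#' Mismatch/expansion report over demes and groups
#'
#' Fits both expansion models to each deme, each group of demes and the
#' pooled sample, and converts parameters to natural units; the layout
#' mirrors a per-population summary table of expansion statistics.
#'
#' @param a an `hd_alignment`.
#' @param rm a [rate_model()].
#' @param n_boot bootstrap replicates for P_SSD.
#' @param seed integer seed.
#' @param min_n smallest subset size analysed.
#' @return data.frame, one row per unit.
#' @export
mismatch_report <- function(a, rm = rate_model(), n_boot = 200, seed = 1,
                            min_n = 4) {
  units <- lapply(unique(unname(a$deme_of)), function(d)
    list(name = d, demes = d))
  if (!is.null(a$group_of)) {
    for (g in unique(unname(a$group_of)))
      units <- c(units, list(list(name = g,
                                  demes = names(a$group_of)[a$group_of == g])))
  }
  units <- c(units, list(list(name = "All", demes = unique(unname(a$deme_of)))))
  L <- ncol(a$seqs)
  rows <- list()
  for (u in units) {
    ids <- a$ids[a$deme_of[a$ids] %in% u$demes]
    if (length(ids) < min_n) next
    om <- observed_mismatch(a, ids)
    fd <- fit_demographic(om$probs, om$n, L = L, n_boot = n_boot, seed = seed)
    fs <- fit_spatial(om$probs, om$n, L = L, n_boot = n_boot, seed = seed + 1)
    cd <- to_natural_units(fd, rm)
    cs <- to_natural_units(fs, rm)
    rows[[u$name]] <- data.frame(
      unit = u$name, n = om$n, obs_mean = om$mean,
      dem_tau = fd$tau, dem_T_years = cd$T_years,
      dem_theta0 = fd$theta0, dem_N0 = cd$N0,
      dem_theta1 = fd$theta1, dem_N1 = cd$N1, dem_P_SSD = fd$p_ssd,
      sp_tau = fs$tau, sp_T_years = cs$T_years,
      sp_theta = fs$theta, sp_N = cs$N, sp_M = fs$M,
      sp_m = cs$m_immigration, sp_P_SSD = fs$p_ssd)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the mismatch/expansion report as TSV
#' @param tab result of [mismatch_report()]
#' @param path output path
#' @return invisibly, the path
#' @export
write_mismatch_report <- function(tab, path) {
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(x) signif(x, 6))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
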
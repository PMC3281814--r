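test_that("HKY pruning likelihood matches the phangorn oracle to 1e-10", {
  skip_if_not_installed("phangorn")
  # fixed 4-taxon genealogy: ((t1:0.02,t2:0.05):0.03,(t3:0.01,t4:0.04):0.07)
  tr <- ape::read.tree(text = "((t1:0.02,t2:0.05):0.03,(t3:0.01,t4:0.04):0.07);")
  set.seed(8)
  seqs <- matrix(sample(c("A", "C", "G", "T"), 4 * 60, replace = TRUE), 4, 60)
  rownames(seqs) <- paste0("t", 1:4)
  kappa <- 3.2
  freqs <- c(A = 0.35, C = 0.15, G = 0.2, T = 0.3)

  dat <- phangorn::phyDat(seqs)
  fit <- phangorn::pml(tr, dat, bf = freqs,
                       Q = c(1, kappa, 1, 1, kappa, 1), k = 1)
  want <- fit$logLik

  # package state: tips 1..4, internal 5 (t1,t2), 6 (t3,t4), root 7
  # times chosen to reproduce the (possibly non-ultrametric) branch lengths
  # after the theta/(2L) scaling: use theta = 2, L = 1, so elen = dt
  st <- list(par = c(5L, 5L, 6L, 6L, 7L, 7L, 0L),
             time = c(0.03, 0, 0, -0.03, 0.05, 0.01, 0.08),
             mig = rep(list(numeric(0)), 7),
             tipdeme = c(1L, 1L, 2L, 2L), theta = 2, M = 0, T = 1,
             theta_max = 10, M_max = 1, T_max = 10)
  pdat <- haplodem:::im_pattern_data(seqs, kappa = kappa)
  pdat$eig <- haplodem:::hky_eigen(kappa, freqs)
  pdat$L <- 1
  got <- haplodem:::im_loglik(st, pdat)
  expect_lt(abs(got - want), 1e-10)
})

test_that("the structured-coalescent prior rejects inter-deme coalescence below T", {
  base <- list(par = c(5L, 5L, 6L, 6L, 7L, 7L, 0L),
               time = c(0, 0, 0, 0, 0.5, 0.8, 3.5),
               mig = rep(list(numeric(0)), 7),
               tipdeme = c(1L, 1L, 2L, 2L), theta = 1, M = 0, T = 3,
               theta_max = 10, M_max = 5, T_max = 10)
  expect_true(is.finite(haplodem:::im_logprior(base)))
  # swap tips 2 and 4 across the cherries: both coalescences below T are
  # now between demes
  bad <- base
  bad$par <- c(5L, 6L, 6L, 5L, 7L, 7L, 0L)
  expect_identical(haplodem:::im_logprior(bad), -Inf)
  # migration events moving tips 2 and 4 across rescue it, but only when
  # M > 0
  fixed <- bad
  fixed$mig[[2]] <- 0.4   # deme 1 -> 2 before joining tip 3 at node 6
  fixed$mig[[4]] <- 0.3   # deme 2 -> 1 before joining tip 1 at node 5
  expect_identical(haplodem:::im_logprior(fixed), -Inf)  # M = 0
  fixed$M <- 1
  expect_true(is.finite(haplodem:::im_logprior(fixed)))
  # migration events above T are invalid
  late <- fixed
  late$mig[[2]] <- 3.2
  expect_identical(haplodem:::im_logprior(late), -Inf)
})

test_that("with no data the sampler reproduces its uniform priors", {
  seqs <- matrix("N", 8, 40)
  rownames(seqs) <- sprintf("i%02d", 1:8)
  a <- hd_alignment(seqs, setNames(rep(c("A", "B"), each = 4),
                                   rownames(seqs)))
  cfg <- im_config(theta_max = 10, M_max = 5, T_max = 4, steps = 120000,
                   thin = 20, n_chains = 1, seed = 17, kappa = 4)
  post <- run_mdiv(a, list("A", "B"), cfg)
  tr <- post$traces[[1]]
  # coarse agreement of the first two moments with Uniform(0, bound)
  expect_equal(mean(tr$theta), 5, tolerance = 0.15)
  expect_equal(mean(tr$M), 2.5, tolerance = 0.2)
  expect_equal(mean(tr$T), 2, tolerance = 0.2)
  expect_equal(sd(tr$theta), 10 / sqrt(12), tolerance = 0.2)
  expect_equal(sd(tr$T), 4 / sqrt(12), tolerance = 0.25)
  expect_true(post$flagged)  # no sequence variation is flagged
})

test_that("a shared monomorphic sample flags theta near zero and flat T", {
  seqs <- matrix("A", 10, 120)
  rownames(seqs) <- sprintf("i%02d", 1:10)
  a <- hd_alignment(seqs, setNames(rep(c("A", "B"), each = 5),
                                   rownames(seqs)))
  cfg <- im_config(theta_max = 8, M_max = 4, T_max = 6, steps = 30000,
                   thin = 20, n_chains = 1, seed = 5, kappa = 4)
  post <- run_mdiv(a, list("A", "B"), cfg)
  expect_true(post$flagged)
  expect_lt(post$modes["theta"], 1.5)  # mass concentrated near zero
})

test_that("TMRCA/T separates common ancestry far predating a shallow split", {
  # under low migration, a shallow split leaves the root age (TMRCA) far
  # above the divergence time, while a deep split pins the root just above
  # it: the per-sample root/T ratio is the isolation diagnostic
  cfg <- im_config(theta_max = 10, M_max = 2, T_max = 8, steps = 25000,
                   thin = 20, n_chains = 1, seed = 23)
  sim_sh <- simulate_coalescent("im_pair", n = c(6, 6), theta = 3, M = 0,
                                T_split = 0.3, L = 800, seed = 301)
  post_sh <- run_mdiv(sim_sh$alignment, list("deme1", "deme2"), cfg)
  tr_sh <- post_sh$traces[[1]]
  sim_dp <- simulate_coalescent("im_pair", n = c(6, 6), theta = 3, M = 0,
                                T_split = 3, L = 800, seed = 302)
  post_dp <- run_mdiv(sim_dp$alignment, list("deme1", "deme2"), cfg)
  tr_dp <- post_dp$traces[[1]]
  ratio_sh <- median(tr_sh$root_time / tr_sh$T)
  ratio_dp <- median(tr_dp$root_time / tr_dp$T)
  expect_gt(ratio_sh, ratio_dp)
})

test_that("natural-unit IM summaries follow the conversion arithmetic", {
  p <- structure(list(modes = c(theta = 0.8, M = 0.5, T = 2, tmrca = 1.2),
                      flagged = FALSE, flag_reason = NULL),
                 class = "im_posterior")
  s <- summarize_im(p, rate_model(u_seq = 2e-5), generations = c(1, 10))
  # N_ef spans exactly 10x between the generation-time endpoints
  expect_equal(s$table$N_ef[1] / s$table$N_ef[2], 10)
  expect_equal(s$table$N_ef[1], 0.8 / (2 * 2e-5))
  # calendar conversions depend on the yearly rate only
  expect_equal(unique(s$table$T_years), 2 * 0.8 / (2 * 2e-5))
  expect_equal(unique(s$table$TMRCA_years), 1.2 / 2e-5)
  expect_equal(s$tmrca_over_T, (1.2 * 2 / 0.8) / 2)
})
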
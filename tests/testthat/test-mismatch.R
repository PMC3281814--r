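test_that("expected mismatch curves are proper distributions", {
  for (pars in list(c(5, 0.5, 50), c(0.5, 0.01, 3), c(20, 2, 200))) {
    f <- expected_mismatch_demographic(400, pars[1], pars[2], pars[3])
    expect_true(all(f >= 0))
    expect_equal(sum(f), 1, tolerance = 1e-6)
  }
  for (pars in list(c(6, 0.9, 1), c(2, 0.1, 50), c(10, 3, 0.2))) {
    f <- expected_mismatch_spatial(400, pars[1], pars[2], pars[3])
    expect_true(all(f >= 0))
    expect_equal(sum(f), 1, tolerance = 1e-6)
  }
  # tau = 0 collapses to the stationary geometric distribution
  f0 <- expected_mismatch_demographic(50, 0, 2, 10)
  expect_equal(f0, 2^(0:50) / 3^(1:51), tolerance = 1e-12)
})

test_that("large M spatial expansion approaches the matched demographic shape", {
  sp <- expected_mismatch_spatial(40, 4, 1, 5000)
  dem <- expected_mismatch_demographic(40, 4, 1, 1e9)
  expect_lt(max(abs(sp - dem)), 1e-3)
})

test_that("observed mismatch matches pi and known point masses", {
  a <- tiny_alignment(rep("ACGTACGT", 4), rep("d", 4))
  om <- observed_mismatch(a)
  expect_equal(unname(om$probs), 1)
  expect_equal(om$mean, 0)

  h1 <- strrep("A", 60); h2 <- paste0(strrep("G", 5), strrep("A", 55))
  b <- tiny_alignment(c(rep(h1, 9), h2), rep("d", 10))
  omb <- observed_mismatch(b)
  expect_equal(omb$mean, 1.000)
  expect_equal(unname(omb$probs[c("0", "5")]), c(36 / 45, 9 / 45))

  sim <- simulate_coalescent("panmictic", n = 15, theta = 3, L = 500, seed = 31)
  expect_equal(observed_mismatch(sim$alignment)$mean,
               pairwise_difference_stats(sim$alignment)$pi)
})

test_that("noise-free curve fits recover the generating parameters", {
  obs <- expected_mismatch_demographic(40, tau = 5, theta0 = 0.5, theta1 = 50)
  f <- haplodem:::fit_expansion_curve(obs / sum(obs), "demographic")
  expect_equal(f$tau, 5, tolerance = 0.10)

  obs2 <- expected_mismatch_spatial(40, tau = 6, theta = 0.9, M = 1)
  f2 <- haplodem:::fit_expansion_curve(obs2 / sum(obs2), "spatial")
  expect_equal(f2$tau, 6, tolerance = 0.15)
  expect_equal(f2$theta, 0.9, tolerance = 0.15)
  expect_equal(f2$M, 1, tolerance = 0.15)
})

test_that("a stationary mismatch leaves tau effectively unidentified", {
  obs <- haplodem:::fhat_stationary(0:40, 3)
  f <- haplodem:::fit_expansion_curve(obs / sum(obs), "demographic")
  # fit degenerates to theta0 ~ theta1 ~ 3 or tau ~ 0: the curve itself is
  # reproduced essentially exactly either way
  expect_lt(f$ssd, 1e-6)
})

test_that("natural-unit conversions reproduce the published arithmetic", {
  rm_ <- rate_model(u_seq = 2e-5, generation_years = 1)
  fit_fo <- structure(list(model = "demographic", tau = 8.996, theta0 = 0,
                           theta1 = 1.740), class = "hd_mismatch_fit")
  cv <- to_natural_units(fit_fo, rm_)
  expect_equal(cv$T_years, 224900)
  fit_alb <- structure(list(model = "demographic", tau = 5.501,
                            theta0 = 0.002, theta1 = 2.338),
                       class = "hd_mismatch_fit")
  expect_equal(to_natural_units(fit_alb, rm_)$N1, 58450)
  fit_corfu <- structure(list(model = "demographic", tau = 0.576,
                              theta0 = 0.627, theta1 = 9999),
                         class = "hd_mismatch_fit")
  expect_equal(to_natural_units(fit_corfu, rm_)$N0, 15675)
  fit_ave <- structure(list(model = "spatial", tau = 0.334, theta = 0.065,
                            M = 9999), class = "hd_mismatch_fit")
  cva <- to_natural_units(fit_ave, rm_)
  expect_equal(cva$T_years, 8350)
  expect_equal(cva$N, 1625)
  fit_albs <- structure(list(model = "spatial", tau = 3.901, theta = 0.902,
                             M = 1.057), class = "hd_mismatch_fit")
  expect_equal(to_natural_units(fit_albs, rm_)$m_immigration,
               1.057 / (2 * 22550), tolerance = 1e-6)
  zero <- structure(list(model = "demographic", tau = 0, theta0 = 1,
                         theta1 = 1), class = "hd_mismatch_fit")
  expect_equal(to_natural_units(zero, rm_)$T_years, 0)
  expect_error(rate_model(u_seq = 0), "positive")
})

test_that("coalescent-simulated expansions are accepted by the bootstrap fit", {
  # P_SSD should be non-significant for most replicates when the model is
  # true
  ok <- 0
  n_rep <- 10
  for (r in seq_len(n_rep)) {
    sim <- simulate_coalescent("sudden_expansion", n = 20, L = 1000, tau = 4,
                               theta0 = 0.2, theta1 = 40, seed = 900 + r)
    om <- observed_mismatch(sim$alignment)
    fit <- fit_demographic(om$probs, om$n, L = 1000, n_boot = 25,
                           seed = 900 + r)
    if (is.na(fit$p_ssd) || fit$p_ssd > 0.05) ok <- ok + 1
  }
  expect_gte(ok / n_rep, 0.7)
})

test_that("Ewens haplotype-count probabilities match brute-force enumeration", {
  # exact check against direct Stirling-number computation for small n
  stirling <- function(n, k) {
    if (n == 0 && k == 0) return(1)
    if (n == 0 || k == 0) return(0)
    (n - 1) * stirling(n - 1, k) + stirling(n - 1, k - 1)
  }
  for (n in c(5, 8)) for (theta in c(0.5, 1, 2)) {
    den <- prod(theta + 0:(n - 1))
    pk <- vapply(1:n, function(k) stirling(n, k) * theta^k / den, 0)
    expect_equal(sum(pk), 1, tolerance = 1e-12)
    for (k in 1:n) {
      expect_equal(ewens_p_at_least(k, n, theta), sum(pk[k:n]) / sum(pk),
                   tolerance = 1e-10)
    }
  }
})

test_that("Fu's FS flags monomorphic data and is calibrated under neutrality", {
  a <- tiny_alignment(rep("AAAA", 5), rep("d", 5))
  r <- fu_fs(a, n_sim = 0)
  expect_true(is.na(r$FS))

  # n = 5, k = 2, pi = 1: FS from the exact Ewens tail
  sp <- ewens_p_at_least(2, 5, 1)
  expect_equal(haplodem:::fs_from_summary(2, 5, 1), log(sp / (1 - sp)))

  # neutral data should rarely be called significant at the 0.02 convention
  hits <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    sim <- simulate_coalescent("panmictic", n = 15, theta = 2, L = 600,
                               seed = 1200 + r)
    ft <- fu_fs(sim$alignment, n_sim = 150, seed = r)
    if (!is.na(ft$p) && ft$p < 0.02) hits <- hits + 1
  }
  expect_lte(hits / n_rep, 0.125)
})

test_that("bootstrap P_SSD is roughly uniform under the fitted model class", {
  pv <- vapply(1:15, function(r) {
    sim <- simulate_coalescent("sudden_expansion", n = 15, L = 800, tau = 4,
                               theta0 = 0.2, theta1 = 30, seed = 2200 + r)
    om <- observed_mismatch(sim$alignment)
    fit_demographic(om$probs, om$n, L = 800, n_boot = 25, seed = r)$p_ssd
  }, 0)
  pv <- pv[!is.na(pv)]
  # coarse check: mass is not piled on either extreme
  expect_gt(mean(pv), 0.2)
  expect_lt(mean(pv), 0.8)
  expect_gt(mean(pv > 0.05), 0.6)
})
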
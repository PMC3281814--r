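test_that("one-level AMOVA components equal the brute-force EMS solution", {
  set.seed(5)
  for (r in 1:5) {
    n <- sample(6:12, 1)
    deme <- factor(sample(paste0("d", 1:3), n, replace = TRUE))
    while (nlevels(droplevels(deme)) < 3 || any(table(deme) < 2)) {
      deme <- factor(sample(paste0("d", 1:3), n, replace = TRUE))
    }
    d2 <- matrix(0, n, n)
    d2[upper.tri(d2)] <- sample(0:10, sum(upper.tri(d2)), replace = TRUE)
    d2 <- d2 + t(d2)
    got <- haplodem:::amova_one_level(d2, deme)
    want <- brute_amova_one(d2, deme)
    expect_equal(unname(got$var_components["Va"]), want$Va, tolerance = 1e-12)
    expect_equal(unname(got$var_components["Vb"]), want$Vb, tolerance = 1e-12)
    expect_equal(unname(got$fixation["F_ST"]), want$F_ST, tolerance = 1e-12)
  }
})

test_that("hand-built 3+3 distance matrix gives hand-computed components", {
  # two demes of 3; within-deme distances all 1, between-deme all 4
  d2 <- matrix(4, 6, 6)
  d2[1:3, 1:3] <- 1; d2[4:6, 4:6] <- 1
  diag(d2) <- 0
  deme <- rep(c("x", "y"), each = 3)
  # SS(total) = (6*1*2 + 9*4*... ) computed by hand:
  # sum over full matrix = 2*(6*1) + 2*(9*4) = 84; SST = 84/12 = 7
  # within: each deme sum = 6 -> 6/6 = 1, so SSW = 2, SSA = 5
  # Vb = 2/4 = 0.5; nc = (6 - 18/6)/1 = 3; Va = (5/1 - 0.5)/3 = 1.5
  got <- haplodem:::amova_one_level(d2, factor(deme))
  expect_equal(unname(got$var_components), c(1.5, 0.5))
  expect_equal(unname(got$fixation["F_ST"]), 0.75)
})

test_that("two-level AMOVA satisfies the fixation-index identity and EMS oracle", {
  set.seed(9)
  for (r in 1:5) {
    deme <- rep(paste0("d", 1:4), times = sample(2:4, 4, replace = TRUE))
    group <- ifelse(deme %in% c("d1", "d2"), "g1", "g2")
    n <- length(deme)
    d2 <- matrix(0, n, n)
    d2[upper.tri(d2)] <- sample(0:12, sum(upper.tri(d2)), replace = TRUE)
    d2 <- d2 + t(d2)
    got <- haplodem:::amova_two_level(d2, factor(deme), factor(group))
    want <- brute_amova_two(d2, deme, group)
    expect_equal(unname(got$var_components), c(want$Va, want$Vb, want$Vc),
                 tolerance = 1e-12)
    f <- got$fixation
    expect_equal((1 - f[["F_CT"]]) * (1 - f[["F_SC"]]), 1 - f[["F_ST"]],
                 tolerance = 1e-12)
  }
  # the identity also holds with the printed study indices (3-decimal
  # rounding of the published table)
  expect_equal((1 - 0.806) * (1 - 0.639), 1 - 0.929, tolerance = 0.02)
})

test_that("amova() on a panmictic pool split at random gives F_ST near zero", {
  sim <- simulate_coalescent("panmictic", n = 24, theta = 3, L = 500,
                             seed = 14)
  a <- sim$alignment
  a$deme_of[] <- rep(c("d1", "d2", "d3"), 8)
  am <- amova(a, grouping = NULL, n_perm = 200, seed = 1)
  expect_lt(abs(am$fixation["F_ST"]), 0.25)
  expect_gt(am$pvals["F_ST"], 0.05)
})

test_that("grouped AMOVA on the study fixture puts most variance among groups", {
  fx <- make_study_fixture(seed = 4)
  am <- amova(fx$alignment, n_perm = 100, seed = 2)
  expect_gt(am$pct_variation[1], 50)
  expect_equal(sum(am$pct_variation), 100, tolerance = 0.1)
  f <- am$fixation
  expect_equal((1 - f[["F_CT"]]) * (1 - f[["F_SC"]]), 1 - f[["F_ST"]],
               tolerance = 1e-12)
})

test_that("pairwise PhiST separates identical and fixed demes correctly", {
  # two demes drawn from one pool: PhiST near 0, non-significant
  sim <- simulate_coalescent("panmictic", n = 20, theta = 3, L = 500, seed = 8)
  a <- sim$alignment
  a$deme_of[] <- rep(c("p1", "p2"), 10)
  ph <- pairwise_phist(a, n_perm = 200, seed = 3)
  expect_lt(abs(ph$phist["p1", "p2"]), 0.15)
  expect_gt(ph$pvals["p1", "p2"], 0.05)
  expect_equal(diag(ph$phist), c(p1 = 0, p2 = 0))

  # demes fixed for haplotypes 10 sites apart: PhiST = 1
  h1 <- strrep("A", 40); h2 <- paste0(strrep("C", 10), strrep("A", 30))
  b <- tiny_alignment(c(rep(h1, 5), rep(h2, 5)), rep(c("x", "y"), each = 5))
  phb <- pairwise_phist(b, n_perm = 100, seed = 1)
  expect_equal(unname(phb$phist["x", "y"]), 1)
  expect_true(phb$significant["x", "y"])
})

test_that("PhiST increases with planted split depth", {
  phis <- vapply(c(0.5, 2, 6), function(Tsplit) {
    sim <- simulate_coalescent("im_pair", n = c(10, 10), theta = 2, M = 0,
                               T_split = Tsplit, L = 800, seed = 21)
    ph <- pairwise_phist(sim$alignment, n_perm = 0, seed = 1)
    ph$phist[1, 2]
  }, 0)
  expect_true(all(diff(phis) > 0))
})

test_that("sequential Bonferroni follows the Holm step-down procedure", {
  sb <- sequential_bonferroni(rep(1, 21))
  expect_false(any(sb$flags))
  expect_equal(sb$thresholds[1], 0.05 / 21)
  expect_equal(round(sb$thresholds[1], 4), 0.0024)

  # hand Holm: 0.05/3, 0.05/2, 0.05/1
  sb2 <- sequential_bonferroni(c(0.001, 0.02, 0.03), alpha = 0.05)
  expect_equal(sb2$flags, c(TRUE, TRUE, TRUE))
  sb3 <- sequential_bonferroni(c(0.03, 0.001, 0.03), alpha = 0.05)
  expect_equal(sb3$flags, c(FALSE, TRUE, FALSE))
  # stop at first failure even if later p would pass its threshold
  sb4 <- sequential_bonferroni(c(0.001, 0.04, 0.045), alpha = 0.05)
  expect_equal(sb4$flags, c(TRUE, FALSE, FALSE))
})

test_that("PhiST permutation p-values are uniform under panmixia", {
  # diversity high enough that the statistic is effectively continuous
  # (sparse data leave ties, which make permutation p-values conservative)
  pv <- vapply(1:60, function(r) {
    sim <- simulate_coalescent("panmictic", n = 16, theta = 8, L = 3000,
                               seed = 5000 + r)
    a <- sim$alignment
    a$deme_of[] <- rep(c("p1", "p2"), each = 8)
    ph <- pairwise_phist(a, n_perm = 99, seed = r)
    ph$pvals[1, 2]
  }, 0)
  pv <- pv[!is.na(pv)]
  u <- (pv * 99 + runif(length(pv))) / 100   # smooth the permutation grid
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})
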
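test_that("haversine distances use the 6371 km earth radius", {
  co <- data.frame(deme = c("a", "b"), lat = c(0, 0), lon = c(0, 1))
  d <- geo_distances(co)
  expect_equal(d["a", "b"], 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(diag(d), c(a = 0, b = 0))
  # the two neighbouring island demes fall in the smallest distance class
  co2 <- data.frame(deme = c("KO3", "KO4"), lat = c(39.616, 39.628),
                    lon = c(19.820, 19.831))
  d2 <- geo_distances(co2)
  expect_equal(unname(d2["KO3", "KO4"]), 1.63, tolerance = 0.02)
  expect_error(geo_distances(data.frame(deme = "x", lat = 99, lon = 0)),
               "latitude")
})

test_that("correlogram r is near zero when genetics is independent of geography", {
  set.seed(2)
  n <- 40
  gd <- matrix(0, n, n)
  gd[upper.tri(gd)] <- sample(0:8, sum(upper.tri(gd)), replace = TRUE)
  gd <- gd + t(gd)
  geo <- matrix(0, n, n)
  geo[upper.tri(geo)] <- runif(sum(upper.tri(geo)), 0, 100)
  geo <- geo + t(geo)
  cg <- spatial_autocorrelogram(gd, geo, class_size_km = 25, n_perm = 99,
                                n_boot = 50, seed = 3)
  expect_true(all(abs(cg$classes$r) < 0.15, na.rm = TRUE))
})

test_that("stepping-stone divergence yields positive short-range r with a sign change", {
  # 1-D lattice of 5 demes; genetic distance grows with lattice distance
  n_per <- 6; k <- 5
  deme_ix <- rep(1:k, each = n_per)
  n <- length(deme_ix)
  gd <- outer(deme_ix, deme_ix, function(a, b) abs(a - b) * 4)
  geo <- outer(deme_ix, deme_ix, function(a, b) abs(a - b) * 10)
  cg <- spatial_autocorrelogram(gd, geo, class_size_km = 10, n_perm = 99,
                                n_boot = 0, seed = 5)
  r <- cg$classes$r
  expect_gt(r[1], 0)
  expect_lt(r[length(r)], 0)
  expect_equal(sum(diff(sign(r[!is.na(r)])) != 0), 1)   # single sign change
  expect_false(is.na(cg$x_intercept))
  expect_gt(cg$classes$p_perm[1], 0)  # defined
})

test_that("a two-cluster toy matches the direct codistance formula", {
  # two tight clusters far apart; first-class r computed directly
  deme_ix <- rep(1:2, each = 4)
  gd <- outer(deme_ix, deme_ix, function(a, b) ifelse(a == b, 0, 6))
  geo <- outer(deme_ix, deme_ix, function(a, b) ifelse(a == b, 1, 500))
  cg <- spatial_autocorrelogram(gd, geo, class_size_km = 10, n_perm = 0,
                                n_boot = 0, seed = 1)
  cmat <- haplodem:::codistance_matrix(gd)
  sel <- which(geo <= 10 & upper.tri(geo), arr.ind = TRUE)
  r_direct <- sum(cmat[sel]) /
    sum(sqrt(diag(cmat)[sel[, 1]] * diag(cmat)[sel[, 2]]))
  expect_equal(cg$classes$r[1], r_direct)
  expect_equal(cg$classes$r[1], 1)  # maximal within-class similarity
})

test_that("r is invariant to rescaling all genetic distances", {
  set.seed(13)
  n <- 20
  gd <- matrix(0, n, n)
  gd[upper.tri(gd)] <- sample(1:9, sum(upper.tri(gd)), replace = TRUE)
  gd <- gd + t(gd)
  geo <- matrix(0, n, n)
  geo[upper.tri(geo)] <- runif(sum(upper.tri(geo)), 0, 60)
  geo <- geo + t(geo)
  c1 <- spatial_autocorrelogram(gd, geo, 20, n_perm = 0, n_boot = 0, seed = 1)
  c2 <- spatial_autocorrelogram(3.7 * gd, geo, 20, n_perm = 0, n_boot = 0,
                                seed = 1)
  expect_equal(c1$classes$r, c2$classes$r, tolerance = 1e-12)
})

test_that("mantel test matches direct correlation and the vegan implementation", {
  set.seed(4)
  k <- 7
  m1 <- matrix(0, k, k)
  m1[upper.tri(m1)] <- runif(sum(upper.tri(m1)))
  m1 <- m1 + t(m1)
  expect_equal(mantel_test(m1, m1, n_perm = 10, seed = 1)$R, 1)

  px <- sample(k)
  m2 <- m1[px, px]
  got <- mantel_test(m1, m2, n_perm = 99, seed = 2)
  lt <- lower.tri(m1)
  expect_equal(got$R, cor(m1[lt], m2[lt]))
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(stats::as.dist(m1), stats::as.dist(m2),
                      permutations = 99)
  expect_equal(got$R, unname(vg$statistic), tolerance = 1e-12)
  expect_error(mantel_test(m1, matrix(1, k, k)), "degenerate")
})

test_that("mantel and correlogram permutation p-values are uniform under no structure", {
  set.seed(6)
  k <- 8
  pv_m <- vapply(1:60, function(r) {
    m1 <- matrix(0, k, k); m2 <- matrix(0, k, k)
    m1[upper.tri(m1)] <- runif(sum(upper.tri(m1)))
    m2[upper.tri(m2)] <- runif(sum(upper.tri(m2)))
    m1 <- m1 + t(m1); m2 <- m2 + t(m2)
    mantel_test(m1, m2, n_perm = 99, seed = r)$p
  }, 0)
  ks <- suppressWarnings(ks.test(pv_m, "punif"))
  expect_gt(ks$p.value, 0.01)

  n <- 16
  pv_c <- vapply(1:50, function(r) {
    set.seed(700 + r)
    gd <- matrix(0, n, n)
    gd[upper.tri(gd)] <- sample(0:9, sum(upper.tri(gd)), replace = TRUE)
    gd <- gd + t(gd)
    geo <- matrix(0, n, n)
    geo[upper.tri(geo)] <- runif(sum(upper.tri(geo)), 0, 40)
    geo <- geo + t(geo)
    cg <- spatial_autocorrelogram(gd, geo, class_size_km = 10, n_perm = 99,
                                  n_boot = 0, seed = r)
    cg$classes$p_perm[1]
  }, 0)
  ks2 <- suppressWarnings(ks.test(pv_c, "punif"))
  expect_gt(ks2$p.value, 0.01)
})
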
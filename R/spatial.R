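#' Great-circle distance matrix between demes
#'
#' Haversine distances (earth radius 6371 km) between deme coordinates in
#' decimal degrees.
#'
#' @param coords data.frame with columns `deme`, `lat`, `lon`.
#' @return symmetric km matrix with deme labels.
#' @export
geo_distances <- function(coords) {
  if (any(coords$lat < -90 | coords$lat > 90))
    stop("latitude out of range", call. = FALSE)
  if (any(coords$lon < -180 | coords$lon > 180))
    stop("longitude out of range", call. = FALSE)
  k <- nrow(coords)
  m <- matrix(0, k, k, dimnames = list(coords$deme, coords$deme))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    m[i, j] <- m[j, i] <- geosphere::distHaversine(
      c(coords$lon[i], coords$lat[i]), c(coords$lon[j], coords$lat[j]),
      r = 6371000) / 1000
  }
  m
}

# Gower-centered codistance matrix from a squared-distance matrix:
# c_ij = -0.5 * (d2_ij - rowmean_i - rowmean_j + grandmean).
codistance_matrix <- function(d2) {
  rm <- rowMeans(d2)
  -0.5 * (sweep(sweep(d2, 1, rm), 2, rm) + mean(d2))
}

correlogram_r <- function(cmat, class_of, n_classes) {
  r <- rep(NA_real_, n_classes)
  n_pairs <- integer(n_classes)
  diag_c <- diag(cmat)
  for (h in seq_len(n_classes)) {
    sel <- which(class_of == h & upper.tri(class_of), arr.ind = TRUE)
    n_pairs[h] <- nrow(sel)
    if (nrow(sel) == 0L) next
    num <- sum(cmat[sel])
    den <- sum(sqrt(pmax(diag_c[sel[, 1]], 0) * pmax(diag_c[sel[, 2]], 0)))
    r[h] <- if (den > 0) num / den else NA_real_
  }
  list(r = r, n_pairs = n_pairs)
}

#' Multivariate spatial autocorrelogram
#'
#' Smouse-Peakall style multivariate autocorrelation of genetic distance by
#' geographic distance class: the genetic squared-distance matrix is
#' Gower-centered into a codistance matrix C and, for each half-open
#' distance class (lower, upper], the coefficient is
#' r(h) = sum of c_ij over class pairs / sum of sqrt(c_ii c_jj); r lies in
#' `[-1, 1]` and has expectation near 0 without spatial structure.
#' One-sided significance comes from permuting individual locations
#' (rows/columns of the geographic matrix); confidence intervals from
#' bootstrap resampling of pairs within each class; the x-intercept from
#' linear interpolation of r across class midpoints.
#'
#' @param gdist individual-by-individual genetic distance matrix (site
#'   differences; used as squared distances).
#' @param geo individual-by-individual geographic distance matrix (km).
#' @param class_size_km width of the distance classes.
#' @param n_perm location permutations (999 by default).
#' @param n_boot bootstrap replicates for the CIs (1000 by default).
#' @param seed integer seed.
#' @return an `hd_correlogram` data.frame-based list: `classes` data.frame
#'   (upper bound, midpoint, n_pairs, r, p_perm, ci_low, ci_high),
#'   `x_intercept` (km, NA when r never changes sign), `class_size_km`.
#' @export
spatial_autocorrelogram <- function(gdist, geo, class_size_km, n_perm = 999,
                                    n_boot = 1000, seed = 1) {
  stopifnot(nrow(gdist) == nrow(geo), class_size_km > 0)
  n <- nrow(gdist)
  cmat <- codistance_matrix(gdist)
  n_classes <- max(1L, ceiling(max(geo) / class_size_km))
  class_of <- matrix(pmin(pmax(ceiling(geo / class_size_km), 1L), n_classes),
                     n, n)
  obs <- correlogram_r(cmat, class_of, n_classes)
  rng <- local_rng(seed)
  p_perm <- rep(NA_real_, n_classes)
  if (n_perm > 0) {
    cnt <- integer(n_classes)
    non_empty <- which(obs$n_pairs > 0)
    for (b in seq_len(n_perm)) {
      px <- sample(n)
      rp <- correlogram_r(cmat, class_of[px, px], n_classes)$r
      for (h in non_empty)
        if (!is.na(rp[h]) && rp[h] >= obs$r[h]) cnt[h] <- cnt[h] + 1L
    }
    p_perm[non_empty] <- (cnt[non_empty] + 1) / (n_perm + 1)
  }
  ci <- matrix(NA_real_, n_classes, 2)
  if (n_boot > 0) {
    diag_c <- diag(cmat)
    for (h in which(obs$n_pairs > 1)) {
      sel <- which(class_of == h & upper.tri(class_of), arr.ind = TRUE)
      vals_num <- cmat[sel]
      vals_den <- sqrt(pmax(diag_c[sel[, 1]], 0) * pmax(diag_c[sel[, 2]], 0))
      m <- length(vals_num)
      rb <- vapply(seq_len(n_boot), function(b) {
        ix <- sample.int(m, m, replace = TRUE)
        den <- sum(vals_den[ix])
        if (den > 0) sum(vals_num[ix]) / den else NA_real_
      }, 0)
      ci[h, ] <- quantile(rb, c(0.025, 0.975), na.rm = TRUE)
    }
  }
  rng$restore()
  mids <- (seq_len(n_classes) - 0.5) * class_size_km
  x_int <- NA_real_
  rr <- obs$r
  for (h in seq_len(n_classes - 1L)) {
    if (!is.na(rr[h]) && !is.na(rr[h + 1]) && rr[h] > 0 && rr[h + 1] <= 0) {
      x_int <- mids[h] + (mids[h + 1] - mids[h]) * rr[h] / (rr[h] - rr[h + 1])
      break
    }
  }
  structure(list(classes = data.frame(upper_km = seq_len(n_classes) * class_size_km,
                                      mid_km = mids, n_pairs = obs$n_pairs,
                                      r = rr, p_perm = p_perm,
                                      ci_low = ci[, 1], ci_high = ci[, 2]),
                 x_intercept = x_int, class_size_km = class_size_km),
            class = "hd_correlogram")
}

#' @export
print.hd_correlogram <- function(x, ...) {
  cat(sprintf("Spatial autocorrelogram (class size %g km); x-intercept %s km\n",
              x$class_size_km,
              if (is.na(x$x_intercept)) "NA" else sprintf("%.1f", x$x_intercept)))
  print(x$classes, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Expand deme-level distances/coordinates to individuals
#'
#' Assigns each individual the coordinates of its deme and returns the
#' individual-by-individual geographic distance matrix.
#'
#' @param a an `hd_alignment` with `coords` set (or supply `coords`).
#' @param coords optional coordinates data.frame overriding `a$coords`.
#' @return geographic km matrix over individuals in `a$ids` order.
#' @export
individual_geo_distances <- function(a, coords = a$coords) {
  if (is.null(coords)) stop("no coordinates available", call. = FALSE)
  dd <- geo_distances(coords)
  dm <- unname(a$deme_of[a$ids])
  m <- dd[dm, dm]
  dimnames(m) <- list(a$ids, a$ids)
  m
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation R of the off-diagonal elements, with significance
#' from random row/column permutations of the second matrix:
#' p = proportion of permutations with R at least the observed value.
#'
#' @param m1,m2 symmetric conformable matrices (k >= 3).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `R` and `p`.
#' @export
mantel_test <- function(m1, m2, n_perm = 10000, seed = 1) {
  k <- nrow(m1)
  stopifnot(k >= 3, all(dim(m1) == dim(m2)))
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  if (sd(v1) == 0 || sd(m2[lt]) == 0)
    stop("degenerate input: constant distance matrix", call. = FALSE)
  R <- cor(v1, m2[lt])
  rng <- local_rng(seed)
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    px <- sample(k)
    if (cor(v1, m2[px, px][lt]) >= R) cnt <- cnt + 1L
  }
  rng$restore()
  list(R = R, p = cnt / n_perm)
}

#' Write a correlogram as TSV
#' @param x an `hd_correlogram`
#' @param path output path
#' @return invisibly, the path
#' @export
write_correlogram <- function(x, path) {
  write.table(cbind(x$classes, x_intercept_km = x$x_intercept), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
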
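# Small fixtures built in code, shared across test files.

tiny_alignment <- function(seqs, demes, ...) {
  ids <- sprintf("t%02d", seq_along(seqs))
  names(seqs) <- ids
  hd_alignment(seqs, setNames(demes, ids), ...)
}

# independent O(n^2 L) pairwise difference counter (character loop)
brute_pairdiff <- function(seqs) {
  n <- nrow(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    cnt <- 0
    for (s in seq_len(ncol(seqs))) {
      a <- seqs[i, s]; b <- seqs[j, s]
      if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T") &&
          a != b) cnt <- cnt + 1
    }
    d[i, j] <- cnt
  }
  d
}

# brute-force AMOVA variance components: compute sums of squares by
# explicit double loops and solve the expected-mean-squares system with
# solve(); independent of the package's implementation.
brute_amova_one <- function(d2, deme) {
  deme <- as.character(deme)
  N <- length(deme)
  pops <- unique(deme)
  P <- length(pops)
  sst <- 0
  for (i in 1:N) for (j in 1:N) sst <- sst + d2[i, j]
  sst <- sst / (2 * N)
  ssw <- 0
  for (p in pops) {
    ix <- which(deme == p)
    s <- 0
    for (i in ix) for (j in ix) s <- s + d2[i, j]
    ssw <- ssw + s / (2 * length(ix))
  }
  ssa <- sst - ssw
  n_p <- table(deme)[pops]
  nc <- (N - sum(n_p^2) / N) / (P - 1)
  # EMS system: MS_w = Vb ; MS_a = Vb + nc * Va
  A <- rbind(c(0, 1), c(nc, 1))
  b <- c(ssw / (N - P), ssa / (P - 1))
  v <- solve(A, b)
  list(Va = v[1], Vb = v[2], F_ST = v[1] / sum(v))
}

brute_amova_two <- function(d2, deme, group) {
  deme <- as.character(deme); group <- as.character(group)
  N <- length(deme)
  pops <- unique(deme); grps <- unique(group)
  P <- length(pops); G <- length(grps)
  ss_set <- function(ix) {
    s <- 0
    for (i in ix) for (j in ix) s <- s + d2[i, j]
    s / (2 * length(ix))
  }
  sst <- ss_set(1:N)
  ssw <- sum(vapply(pops, function(p) ss_set(which(deme == p)), 0))
  ssg <- sum(vapply(grps, function(g) ss_set(which(group == g)), 0))
  ss_ag <- sst - ssg
  ss_apwg <- ssg - ssw
  n_p <- vapply(pops, function(p) sum(deme == p), 0)
  gr_of <- vapply(pops, function(p) group[match(p, deme)], "")
  N_g <- vapply(grps, function(g) sum(group == g), 0)
  s1 <- sum(vapply(grps, function(g)
    sum(n_p[gr_of == g]^2) / N_g[g], 0))
  n1 <- (N - s1) / (P - G)
  n2 <- (s1 - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(N_g^2) / N) / (G - 1)
  # EMS: MS_w = Vc ; MS_ap = Vc + n1 Vb ; MS_ag = Vc + n2 Vb + n3 Va
  A <- rbind(c(0, 0, 1), c(0, n1, 1), c(n3, n2, 1))
  b <- c(ssw / (N - P), ss_apwg / (P - G), ss_ag / (G - 1))
  v <- solve(A, b)
  list(Va = v[1], Vb = v[2], Vc = v[3],
       F_CT = v[1] / sum(v), F_SC = v[2] / (v[2] + v[3]),
       F_ST = (v[1] + v[2]) / sum(v))
}
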
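#' Unbiased haplotype diversity
#'
#' Sample-size corrected probability that two randomly drawn sequences
#' carry different haplotypes:
#' \deqn{h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}
#' with \eqn{p_i} the relative frequency of haplotype i and n the sample
#' size.
#'
#' @param counts non-negative integer vector of haplotype counts.
#' @return haplotype diversity in `[0, 1]`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2L) stop("input error: need at least 2 sequences", call. = FALSE)
  p <- counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Mean pairwise differences and nucleotide diversity for one deme
#'
#' \eqn{\pi} is the mean number of differing sites over all C(n,2) pairs of
#' individuals in the deme (pairwise deletion of missing data);
#' \eqn{\pi_n = \pi / L} is the nucleotide diversity.
#'
#' @param a an `hd_alignment`.
#' @param deme deme label; `NULL` uses all individuals.
#' @return list with `pi` (sites) and `pi_n` (proportion).
#' @export
pairwise_difference_stats <- function(a, deme = NULL) {
  ids <- if (is.null(deme)) a$ids else a$ids[a$deme_of[a$ids] == deme]
  n <- length(ids)
  if (n < 2L) stop("input error: deme needs at least 2 individuals", call. = FALSE)
  d <- pairwise_diff_matrix(a$seqs[ids, , drop = FALSE])
  pi <- sum(d[upper.tri(d)]) / choose(n, 2)
  list(pi = pi, pi_n = pi / ncol(a$seqs))
}

#' Per-deme molecular diversity table
#'
#' One row per deme with sample size N, haplotype count H, unbiased
#' haplotype diversity h, mean pairwise differences pi and nucleotide
#' diversity pi_n (reported as percent). Demes with fewer than 2
#' individuals get NA diversity values.
#'
#' @param a an `hd_alignment`.
#' @param haps optional pre-computed [collapse_haplotypes()] result.
#' @return data.frame with columns `deme`, `N`, `H`, `h`, `pi`, `pi_n_pct`.
#' @export
diversity_table <- function(a, haps = NULL) {
  if (is.null(haps)) haps <- collapse_haplotypes(a)
  demes <- colnames(haps$counts)
  rows <- lapply(demes, function(dm) {
    cnt <- haps$counts[, dm]
    N <- sum(cnt)
    H <- sum(cnt > 0)
    if (N >= 2L) {
      h <- haplotype_diversity(cnt)
      pd <- pairwise_difference_stats(a, dm)
      data.frame(deme = dm, N = N, H = H, h = h, pi = pd$pi,
                 pi_n_pct = 100 * pd$pi_n)
    } else {
      data.frame(deme = dm, N = N, H = H, h = NA_real_, pi = NA_real_,
                 pi_n_pct = NA_real_)
    }
  })
  do.call(rbind, rows)
}

#' Write the diversity table as TSV
#' @param tab result of [diversity_table()]
#' @param path output path
#' @return invisibly, the path
#' @export
write_diversity_table <- function(tab, path) {
  out <- tab
  out$h <- round(out$h, 3)
  out$pi <- round(out$pi, 3)
  out$pi_n_pct <- round(out$pi_n_pct, 2)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
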
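# Statistical parsimony (TCS-style) haplotype networks.
#
# The connection limit is the largest number of mutational steps j for
# which the probability that a path of j observed differences contains no
# homoplasy still exceeds the confidence level. The package models a chain
# of j successive mutations over L sites under an equal-rate four-state
# model: the i-th mutation strikes one of the i-1 previously mutated sites
# with probability (i-1)/L and then produces a homoplasious (parallel or
# convergent) state with probability 2/3, so
#   P_j = prod_{i=2..j} (1 - 2 (i-1) / (3 L)).
# This calibration reproduces the canonical 13-step limit for a 1,025-site
# mitochondrial alignment at the 95% level.

#' Probability of a homoplasy-free connection of j mutational steps
#'
#' @param j number of mutational steps (scalar or vector).
#' @param L alignment length in sites.
#' @return probability in `[0, 1]` that j observed differences reflect j
#'   single substitutions at distinct sites.
#' @export
parsimony_probability <- function(j, L) {
  stopifnot(L >= 1)
  vapply(j, function(jj) {
    if (jj <= 1) return(1)
    terms <- 1 - 2 * seq_len(jj - 1L) / (3 * L)
    prod(pmax(terms, 0))
  }, 0)
}

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps j such that
#' [parsimony_probability()] of a j-step connection over `L` sites exceeds
#' `confidence`. Haplotype pairs farther apart than this limit are not
#' joined in the network.
#'
#' @param L alignment length in sites.
#' @param confidence parsimony confidence level (default 0.95).
#' @return integer connection limit (>= 1 unless even a single step falls
#'   below `confidence`, which cannot happen for `confidence < 1`).
#' @export
connection_limit <- function(L, confidence = 0.95) {
  stopifnot(L >= 1, confidence > 0, confidence <= 1)
  j <- 1L
  while (parsimony_probability(j + 1L, L) > confidence) j <- j + 1L
  j
}

#' Build a statistical-parsimony haplotype network
#'
#' Agglomerative construction: haplotype pairs are joined at increasing
#' mutational distance d = 1..limit, inserting d-1 anonymous intermediate
#' nodes (unobserved haplotypes) along each new path. Candidate joins at a
#' given distance are processed in decreasing order of joint haplotype
#' frequency, ties broken by label order; a join between haplotypes already
#' connected would create a reticulation and is skipped (the network is
#' frequency-resolved to a forest of trees). Components that cannot be
#' connected within the limit remain separate subnetworks.
#'
#' @param haps an `hd_haplotypes` from [collapse_haplotypes()].
#' @param limit connection limit in steps; default computed from the
#'   alignment length at 95% confidence.
#' @param confidence confidence used when `limit` is NULL.
#' @return an `hd_network` list: `nodes` (data.frame id/type/count),
#'   `edges` (data.frame from/to), `subnetwork` (named membership vector
#'   for observed haplotypes), `limit`, `deme_counts`.
#' @export
build_network <- function(haps, limit = NULL, confidence = 0.95) {
  k <- length(haps$hap_seqs)
  if (k == 0L) stop("input error: empty haplotype table", call. = FALSE)
  if (is.null(limit)) limit <- connection_limit(haps$L, confidence)
  seq_mat <- do.call(rbind, strsplit(unname(haps$hap_seqs), "", fixed = TRUE))
  rownames(seq_mat) <- names(haps$hap_seqs)
  d <- pairwise_diff_matrix(seq_mat)
  freq <- rowSums(haps$counts)
  labs <- names(haps$hap_seqs)

  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nodes <- data.frame(id = labs, type = "observed",
                      count = unname(freq[labs]),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  n_anon <- 0L
  if (k > 1L) for (dd in seq_len(limit)) {
    pairs <- which(d == dd & upper.tri(d), arr.ind = TRUE)
    if (nrow(pairs) == 0L) next
    jf <- freq[pairs[, 1]] + freq[pairs[, 2]]
    ord <- order(-jf, pairs[, 1], pairs[, 2])
    for (r in ord) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      ri <- find(i); rj <- find(j)
      if (ri == rj) next  # reticulation: resolved away
      path <- labs[i]
      if (dd > 1L) for (s in seq_len(dd - 1L)) {
        n_anon <- n_anon + 1L
        anon <- paste0("m", n_anon)
        nodes <- rbind(nodes, data.frame(id = anon, type = "intermediate",
                                         count = 0L))
        edges <- rbind(edges, data.frame(from = path[length(path)], to = anon))
        path <- c(path, anon)
      }
      edges <- rbind(edges, data.frame(from = path[length(path)], to = labs[j]))
      parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(k), find, 0L)
  subnetwork <- setNames(match(comp, unique(comp)), labs)
  structure(list(nodes = nodes, edges = edges, subnetwork = subnetwork,
                 limit = limit, deme_counts = haps$counts),
            class = "hd_network")
}

#' @export
print.hd_network <- function(x, ...) {
  cat(sprintf("hd_network: %d nodes (%d observed), %d edges, %d subnetwork(s), limit %d\n",
              nrow(x$nodes), sum(x$nodes$type == "observed"),
              nrow(x$edges), length(unique(x$subnetwork)), x$limit))
  invisible(x)
}

#' Write a network as node and edge TSV files
#'
#' Node attributes (haplotype id, total count, per-deme composition,
#' subnetwork) and the single-step edge list, in a layout that loads
#' directly into graph tools.
#'
#' @param x an `hd_network`
#' @param nodes_path,edges_path output paths
#' @return invisibly, the paths
#' @export
write_network <- function(x, nodes_path, edges_path) {
  nd <- x$nodes
  nd$subnetwork <- NA_integer_
  obs <- nd$type == "observed"
  nd$subnetwork[obs] <- unname(x$subnetwork[nd$id[obs]])
  comp <- x$deme_counts[nd$id[obs], , drop = FALSE]
  for (dm in colnames(comp)) {
    nd[[dm]] <- 0L
    nd[[dm]][obs] <- comp[, dm]
  }
  write.table(nd, nodes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$edges, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}
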
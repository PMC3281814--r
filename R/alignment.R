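#' @useDynLib haplodem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim pchisq quantile runif rpois rexp rbinom sd setNames
#'   rgamma cor ks.test punif
#' @importFrom utils write.table read.csv head tail
NULL

VALID_BASES <- c("A", "C", "G", "T")

#' Aligned mitochondrial sequences with deme metadata
#'
#' Constructs the central container used by every analysis in the package:
#' an alignment of equal-length nucleotide sequences, a mapping of each
#' individual to a deme, optional deme-level group assignments and
#' geographic coordinates, and named partitions (e.g. the two concatenated
#' gene fragments) that tile the alignment.
#'
#' @param seqs character matrix (individuals x sites) of single upper-case
#'   characters, or a named character vector of sequence strings. Symbols
#'   other than A, C, G, T and "-" are mapped to "N".
#' @param deme_of named character vector mapping individual ids to deme
#'   labels. Every row of `seqs` must be covered.
#' @param partitions named list of integer pairs `c(first, last)` (1-based,
#'   inclusive) tiling `1..L` without overlap. Defaults to one partition
#'   spanning the whole alignment.
#' @param group_of optional named character vector mapping deme labels to
#'   group labels (e.g. the three regional haplogroups).
#' @param coords optional data.frame with columns `deme`, `lat`, `lon` in
#'   decimal degrees.
#' @return an object of class `hd_alignment` with elements `ids`, `seqs`
#'   (character matrix), `partitions`, `deme_of`, `group_of`, `coords`.
#' @export
hd_alignment <- function(seqs, deme_of, partitions = NULL, group_of = NULL,
                         coords = NULL) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    if (is.null(names(seqs))) stop("sequence vector must be named", call. = FALSE)
    L <- unique(nchar(seqs))
    if (length(L) != 1L)
      stop("alignment error: sequences have unequal lengths", call. = FALSE)
    ids <- names(seqs)
    seqs <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
                   nrow = length(seqs), ncol = L, byrow = TRUE,
                   dimnames = list(ids, NULL))
  } else {
    seqs <- toupper(seqs)
    if (is.null(rownames(seqs))) stop("sequence matrix must have rownames", call. = FALSE)
  }
  bad <- !(seqs %in% c(VALID_BASES, "-", "N"))
  if (any(bad)) seqs[bad] <- "N"
  ids <- rownames(seqs)
  L <- ncol(seqs)
  missing_ids <- setdiff(ids, names(deme_of))
  if (length(missing_ids) > 0L)
    stop("metadata error: individuals missing from popmap: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  deme_of <- deme_of[ids]
  if (is.null(partitions)) partitions <- list(all = c(1L, L))
  check_partitions(partitions, L)
  structure(list(ids = ids, seqs = seqs, partitions = partitions,
                 deme_of = deme_of, group_of = group_of, coords = coords),
            class = "hd_alignment")
}

check_partitions <- function(partitions, L) {
  covered <- integer(0)
  for (p in partitions) {
    if (length(p) != 2L || p[1] > p[2])
      stop("partition must be c(first, last) with first <= last", call. = FALSE)
    covered <- c(covered, seq.int(p[1], p[2]))
  }
  if (length(covered) != L || anyDuplicated(covered) || !setequal(covered, seq_len(L)))
    stop("partitions must tile 1..L without overlap", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.hd_alignment <- function(x, ...) {
  cat(sprintf("hd_alignment: %d individuals x %d sites, %d demes, %d partition(s)\n",
              length(x$ids), ncol(x$seqs), length(unique(x$deme_of)),
              length(x$partitions)))
  invisible(x)
}

#' Number of sites in an alignment
#' @param a an `hd_alignment`
#' @return integer alignment length
#' @export
alignment_length <- function(a) ncol(a$seqs)

#' Read an alignment and population map from disk
#'
#' Reads a FASTA alignment plus a two- or three-column popmap CSV
#' (`id,deme[,group]`) and an optional coordinates CSV (`deme,lat,lon`).
#' All FASTA records must be present in the popmap.
#'
#' @param fasta_path path to an aligned FASTA file.
#' @param popmap_path path to the popmap CSV (header required).
#' @param partitions as in [hd_alignment()].
#' @param coords_path optional path to a deme coordinates CSV.
#' @return an `hd_alignment`.
#' @export
read_alignment <- function(fasta_path, popmap_path, partitions = NULL,
                           coords_path = NULL) {
  dna <- ape::read.FASTA(fasta_path)
  seqs <- toupper(vapply(as.character(dna), paste, "", collapse = ""))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment error: FASTA sequences have unequal lengths", call. = FALSE)
  pm <- read.csv(popmap_path, stringsAsFactors = FALSE)
  if (ncol(pm) < 2L) stop("metadata error: popmap needs id and deme columns", call. = FALSE)
  deme_of <- setNames(as.character(pm[[2]]), as.character(pm[[1]]))
  group_of <- NULL
  if (ncol(pm) >= 3L && !all(is.na(pm[[3]]))) {
    gm <- unique(data.frame(deme = as.character(pm[[2]]),
                            group = as.character(pm[[3]])))
    group_of <- setNames(gm$group, gm$deme)
  }
  coords <- NULL
  if (!is.null(coords_path)) {
    coords <- read.csv(coords_path, stringsAsFactors = FALSE)
    names(coords)[1:3] <- c("deme", "lat", "lon")
  }
  hd_alignment(seqs, deme_of, partitions = partitions, group_of = group_of,
               coords = coords)
}

#' Write an alignment with its metadata
#'
#' Writes the FASTA file, popmap CSV and (when coordinates are present) the
#' coordinates CSV. Round-trips through [read_alignment()] byte-identically
#' for gap-free upper-case alignments.
#'
#' @param a an `hd_alignment`.
#' @param fasta_path,popmap_path,coords_path output paths; `coords_path`
#'   is only written when `a$coords` is non-NULL.
#' @return invisibly, the paths written.
#' @export
write_alignment <- function(a, fasta_path, popmap_path, coords_path = NULL) {
  con <- file(fasta_path, "w")
  on.exit(close(con))
  for (i in seq_along(a$ids)) {
    writeLines(paste0(">", a$ids[i]), con)
    writeLines(paste(a$seqs[i, ], collapse = ""), con)
  }
  pm <- data.frame(id = a$ids, deme = unname(a$deme_of[a$ids]))
  if (!is.null(a$group_of)) pm$group <- unname(a$group_of[pm$deme])
  write.csv_plain(pm, popmap_path)
  paths <- c(fasta_path, popmap_path)
  if (!is.null(a$coords) && !is.null(coords_path)) {
    write.csv_plain(a$coords, coords_path)
    paths <- c(paths, coords_path)
  }
  invisible(paths)
}

write.csv_plain <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
}

#' Subset an alignment to a set of individuals or demes
#' @param a an `hd_alignment`
#' @param ids individual ids to keep (default all)
#' @param demes deme labels to keep (applied after `ids`)
#' @return an `hd_alignment` restricted to the selection
#' @export
subset_alignment <- function(a, ids = NULL, demes = NULL) {
  keep <- a$ids
  if (!is.null(ids)) keep <- intersect(keep, ids)
  if (!is.null(demes)) keep <- keep[a$deme_of[keep] %in% demes]
  if (length(keep) == 0L) stop("empty selection", call. = FALSE)
  hd_alignment(a$seqs[keep, , drop = FALSE], a$deme_of[keep],
               partitions = a$partitions, group_of = a$group_of,
               coords = a$coords)
}

#' Collapse an alignment into haplotypes
#'
#' Identical sequences share a haplotype; sequences differing only at sites
#' where one of them carries N (or an ingroup gap) are merged into the
#' earlier haplotype. Haplotypes are numbered H1..Hk in order of first
#' appearance in the alignment.
#'
#' @param a an `hd_alignment`.
#' @return an object of class `hd_haplotypes`: list with `hap_seqs` (named
#'   character vector of representative sequences), `counts` (haplotype x
#'   deme integer matrix), `hap_of` (haplotype label per individual) and
#'   `L` (alignment length).
#' @export
collapse_haplotypes <- function(a) {
  n <- length(a$ids)
  if (n == 0L) stop("empty alignment", call. = FALSE)
  ambiguous <- function(v) v == "N" | v == "-"
  reps <- list()           # representative sequences as char vectors
  hap_of <- character(n)
  for (i in seq_len(n)) {
    s <- a$seqs[i, ]
    placed <- FALSE
    for (k in seq_along(reps)) {
      r <- reps[[k]]
      cmp <- r == s | ambiguous(r) | ambiguous(s)
      if (all(cmp)) {
        # merge; resolve representative ambiguities from the new sequence
        amb <- ambiguous(r) & !ambiguous(s)
        if (any(amb)) reps[[k]][amb] <- s[amb]
        hap_of[i] <- names(reps)[k]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      lab <- paste0("H", length(reps) + 1L)
      reps[[lab]] <- s
      hap_of[i] <- lab
    }
  }
  demes <- unique(unname(a$deme_of))
  counts <- table(factor(hap_of, levels = names(reps)),
                  factor(a$deme_of[a$ids], levels = demes))
  counts <- matrix(as.integer(counts), nrow = length(reps),
                   dimnames = list(names(reps), demes))
  hap_seqs <- vapply(reps, paste, "", collapse = "")
  structure(list(hap_seqs = hap_seqs, counts = counts,
                 hap_of = setNames(hap_of, a$ids), L = ncol(a$seqs)),
            class = "hd_haplotypes")
}

#' @export
print.hd_haplotypes <- function(x, ...) {
  cat(sprintf("hd_haplotypes: %d haplotypes, %d individuals, %d demes\n",
              length(x$hap_seqs), sum(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Write a haplotype frequency table (haplotypes x demes, with margins)
#' @param h an `hd_haplotypes`
#' @param path output TSV path
#' @return invisibly, the path
#' @export
write_haplotype_table <- function(h, path) {
  tab <- cbind(h$counts, Tot. = rowSums(h$counts))
  tab <- rbind(tab, Tot. = colSums(tab))
  d <- data.frame(Haplotype = rownames(tab), tab, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-partition site statistics
#'
#' Counts variable and parsimony-informative columns per partition and
#' overall, and tabulates base composition per taxon and pooled. A column
#' is variable when at least two distinct bases occur (gaps and N are
#' excluded from state counts) and parsimony-informative when at least two
#' states each occur in at least two sequences. Codon sub-partitions of a
#' partition can be requested by supplying its reading frame.
#'
#' @param a an `hd_alignment`.
#' @param codon_partition optional name of a partition to additionally
#'   split by codon position.
#' @param frame reading frame (1, 2 or 3) of the first column of
#'   `codon_partition`; required when `codon_partition` is given.
#' @return list with `per_partition` data.frame (`partition`, `length`,
#'   `n_variable`, `n_parsimony_informative`), `base_freqs` (taxa x 4
#'   proportions) and `pooled_freqs`.
#' @export
site_statistics <- function(a, codon_partition = NULL, frame = NULL) {
  parts <- lapply(a$partitions, function(p) seq.int(p[1], p[2]))
  parts$overall <- seq_len(ncol(a$seqs))
  if (!is.null(codon_partition)) {
    if (is.null(frame))
      stop("reading frame required for codon partitioning", call. = FALSE)
    rng <- a$partitions[[codon_partition]]
    if (is.null(rng)) stop("unknown partition: ", codon_partition, call. = FALSE)
    cols <- seq.int(rng[1], rng[2])
    pos <- ((cols - rng[1] + (frame - 1L)) %% 3L) + 1L
    for (p in 1:3)
      parts[[paste0(codon_partition, "_pos", p)]] <- cols[pos == p]
  }
  # per-base column counts, vectorised over the alignment
  base_counts <- vapply(VALID_BASES,
                        function(b) colSums(a$seqs == b), numeric(ncol(a$seqs)))
  n_states <- rowSums(base_counts >= 1L)
  n_shared <- rowSums(base_counts >= 2L)
  scan_cols <- function(cols) {
    c(sum(n_states[cols] >= 2L),
      sum(n_states[cols] >= 2L & n_shared[cols] >= 2L))
  }
  rows <- lapply(names(parts), function(nm) {
    cols <- parts[[nm]]
    st <- scan_cols(cols)
    data.frame(partition = nm, length = length(cols),
               n_variable = st[1], n_parsimony_informative = st[2])
  })
  per_partition <- do.call(rbind, rows)
  bf <- t(apply(a$seqs, 1, function(s) {
    s <- s[s %in% VALID_BASES]
    tabulate(match(s, VALID_BASES), 4L) / max(length(s), 1L)
  }))
  colnames(bf) <- VALID_BASES
  pooled <- {
    s <- a$seqs[a$seqs %in% VALID_BASES]
    setNames(tabulate(match(s, VALID_BASES), 4L) / length(s), VALID_BASES)
  }
  list(per_partition = per_partition, base_freqs = bf, pooled_freqs = pooled)
}

#' Chi-square test of base-frequency homogeneity across taxa
#'
#' Contingency chi-square on the taxa x 4 table of base counts (gaps and N
#' excluded), with df = (n_taxa - 1) * 3 as used for compositional
#' homogeneity screens of aligned sequences.
#'
#' @param a an `hd_alignment`.
#' @return list with `chi2`, `df`, `p` and the count `table`.
#' @export
base_homogeneity_chi2 <- function(a) {
  n <- length(a$ids)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  counts <- t(apply(a$seqs, 1, function(s) {
    s <- s[s %in% VALID_BASES]
    tabulate(match(s, VALID_BASES), 4L)
  }))
  colnames(counts) <- VALID_BASES
  if (any(rowSums(counts) == 0L))
    stop("input error: taxon with no countable bases", call. = FALSE)
  rs <- rowSums(counts); cs <- colSums(counts); tot <- sum(counts)
  expected <- outer(rs, cs) / tot
  keep <- expected > 0
  chi2 <- sum((counts[keep] - expected[keep])^2 / expected[keep])
  df <- (n - 1L) * 3L
  p <- pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p, table = counts)
}

#' Pairwise difference matrix between sequences
#'
#' Number of differing sites for every pair, with pairwise deletion of
#' sites where either sequence carries N or a gap. This raw count is the
#' genetic distance used throughout the package (diversity, PhiST/AMOVA,
#' mismatch distributions, correlograms).
#'
#' @param seqs character matrix (individuals x sites) or an `hd_alignment`.
#' @return symmetric numeric matrix of site differences.
#' @export
pairwise_diff_matrix <- function(seqs) {
  if (inherits(seqs, "hd_alignment")) seqs <- seqs$seqs
  n <- nrow(seqs)
  ok <- seqs %in% VALID_BASES
  dim(ok) <- dim(seqs)
  d <- matrix(0, n, n, dimnames = list(rownames(seqs), rownames(seqs)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    si <- seqs[i, ]; oi <- ok[i, ]
    for (j in seq.int(i + 1L, n)) {
      use <- oi & ok[j, ]
      d[i, j] <- d[j, i] <- sum(si[use] != seqs[j, use])
    }
  }
  d
}
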
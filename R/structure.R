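# Analysis of molecular variance on squared pairwise distances
# (Excoffier-Quattro-Smouse framework). For haplotype sequence data the
# squared distance between two individuals is their raw count of differing
# sites, so sums of squares are computed directly from the difference
# matrix.

ssd_within <- function(d2, idx) {
  # (1/2n) * sum over the full sub-matrix == sum over pairs / n
  if (length(idx) == 0L) return(0)
  sum(d2[idx, idx]) / (2 * length(idx))
}

amova_one_level <- function(d2, deme) {
  N <- length(deme)
  pops <- split(seq_len(N), deme)
  P <- length(pops)
  ssd_t <- ssd_within(d2, seq_len(N))
  ssd_wp <- sum(vapply(pops, function(ix) ssd_within(d2, ix), 0))
  ssd_ap <- ssd_t - ssd_wp
  df_ap <- P - 1L
  df_wp <- N - P
  n_p <- lengths(pops)
  n_c <- (N - sum(n_p^2) / N) / (P - 1)
  Vb <- ssd_wp / df_wp
  Va <- (ssd_ap / df_ap - Vb) / n_c
  list(ss = c(among_populations = ssd_ap, within_populations = ssd_wp),
       df = c(among_populations = df_ap, within_populations = df_wp),
       var_components = c(Va = Va, Vb = Vb),
       fixation = c(F_ST = Va / (Va + Vb)))
}

amova_two_level <- function(d2, deme, group) {
  N <- length(deme)
  pops <- split(seq_len(N), deme)
  grps <- split(seq_len(N), group)
  P <- length(pops); G <- length(grps)
  group_of_pop <- vapply(pops, function(ix) as.character(group[ix[1]]), "")
  ssd_t <- ssd_within(d2, seq_len(N))
  ssd_wp <- sum(vapply(pops, function(ix) ssd_within(d2, ix), 0))
  ssd_wg <- sum(vapply(grps, function(ix) ssd_within(d2, ix), 0))
  ssd_ap_wg <- ssd_wg - ssd_wp
  ssd_ag <- ssd_t - ssd_wg
  df_ag <- G - 1L; df_ap <- P - G; df_wp <- N - P
  n_p <- lengths(pops)
  N_g <- lengths(grps)
  sum_np2_over_Ng <- sum(vapply(names(grps), function(g) {
    sum(n_p[group_of_pop == g]^2) / N_g[g]
  }, 0))
  n1 <- (N - sum_np2_over_Ng) / (P - G)
  n2 <- (sum_np2_over_Ng - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(N_g^2) / N) / (G - 1)
  Vc <- ssd_wp / df_wp
  Vb <- (ssd_ap_wg / df_ap - Vc) / n1
  Va <- (ssd_ag / df_ag - Vc - n2 * Vb) / n3
  Vtot <- Va + Vb + Vc
  list(ss = c(among_groups = ssd_ag, among_populations = ssd_ap_wg,
              within_populations = ssd_wp),
       df = c(among_groups = df_ag, among_populations = df_ap,
              within_populations = df_wp),
       var_components = c(Va = Va, Vb = Vb, Vc = Vc),
       fixation = c(F_CT = Va / Vtot, F_SC = Vb / (Vb + Vc),
                    F_ST = (Va + Vb) / Vtot))
}

#' Analysis of molecular variance (AMOVA)
#'
#' Partitions squared pairwise sequence distances into variance components
#' within demes, among demes (within groups) and, for the two-level
#' design, among groups, with the associated fixation indices F_ST (and
#' F_SC, F_CT). Significance is assessed by permutation: individuals among
#' demes for F_ST, individuals among demes within groups for F_SC, and
#' whole demes among groups for F_CT; each p-value is the proportion of
#' permuted statistics greater than or equal to the observed one. Negative
#' variance components are retained, not truncated.
#'
#' @param a an `hd_alignment`.
#' @param grouping optional named character vector mapping deme labels to
#'   groups (defaults to `a$group_of`); `NULL` and no stored groups give
#'   the one-level design.
#' @param n_perm number of permutations (0 skips the tests).
#' @param seed integer seed for the permutation stream.
#' @param d2 optional pre-computed squared-distance (site difference)
#'   matrix in the row order of `a$ids`.
#' @return an `hd_amova` list: `design`, `ss`, `df`, `var_components`,
#'   `pct_variation`, `fixation`, `pvals`.
#' @export
amova <- function(a, grouping = a$group_of, n_perm = 10000, seed = 1,
                  d2 = NULL) {
  if (is.null(d2)) d2 <- pairwise_diff_matrix(a)
  deme <- factor(unname(a$deme_of[a$ids]))
  if (nlevels(deme) < 2L) stop("need at least 2 demes", call. = FALSE)
  if (any(table(deme) < 2L))
    warning("singleton deme present: degrees of freedom degrade")
  rng <- local_rng(seed)
  if (is.null(grouping)) {
    obs <- amova_one_level(d2, deme)
    pv <- c(F_ST = NA_real_)
    if (n_perm > 0) {
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        perm <- amova_one_level(d2, sample(deme))$fixation["F_ST"]
        if (!is.na(perm) && perm >= obs$fixation["F_ST"]) cnt <- cnt + 1L
      }
      pv["F_ST"] <- if (is.na(obs$fixation["F_ST"])) NA_real_ else cnt / n_perm
    }
    res <- c(obs, list(design = "one-level", pvals = pv))
  } else {
    group <- factor(unname(grouping[as.character(deme)]))
    if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
    obs <- amova_two_level(d2, deme, group)
    pv <- c(F_CT = NA_real_, F_SC = NA_real_, F_ST = NA_real_)
    if (n_perm > 0) {
      cnt <- c(F_CT = 0L, F_SC = 0L, F_ST = 0L)
      pops <- levels(deme)
      group_of_pop <- grouping[pops]
      for (b in seq_len(n_perm)) {
        # F_ST: individuals among demes, ignoring groups
        deme_p <- sample(deme)
        grp_p <- factor(unname(grouping[as.character(deme_p)]))
        f <- amova_two_level(d2, deme_p, grp_p)$fixation
        if (f["F_ST"] >= obs$fixation["F_ST"]) cnt["F_ST"] <- cnt["F_ST"] + 1L
        # F_SC: individuals among demes within groups
        deme_sc <- deme
        for (g in levels(group)) {
          ix <- which(group == g)
          deme_sc[ix] <- deme[ix][sample(length(ix))]
        }
        f <- amova_two_level(d2, deme_sc, group)$fixation
        if (f["F_SC"] >= obs$fixation["F_SC"]) cnt["F_SC"] <- cnt["F_SC"] + 1L
        # F_CT: whole demes among groups
        gop <- setNames(sample(unname(group_of_pop)), pops)
        grp_ct <- factor(unname(gop[as.character(deme)]))
        if (nlevels(grp_ct) >= 2L) {
          f <- amova_two_level(d2, deme, grp_ct)$fixation
          if (f["F_CT"] >= obs$fixation["F_CT"]) cnt["F_CT"] <- cnt["F_CT"] + 1L
        }
      }
      pv <- cnt / n_perm
    }
    res <- c(obs, list(design = "two-level", pvals = pv))
  }
  rng$restore()
  tot <- sum(res$var_components)
  res$pct_variation <- 100 * res$var_components / tot
  class(res) <- "hd_amova"
  res
}

#' @export
print.hd_amova <- function(x, ...) {
  cat(sprintf("AMOVA (%s design)\n", x$design))
  strata <- names(x$ss)
  for (s in strata)
    cat(sprintf("  %-22s SS = %8.2f  df = %3d\n", s, x$ss[s], x$df[s]))
  for (i in seq_along(x$var_components))
    cat(sprintf("  %s = %.4f (%.2f%%)\n", names(x$var_components)[i],
                x$var_components[i], x$pct_variation[i]))
  for (i in seq_along(x$fixation))
    cat(sprintf("  %s = %.4f  (P = %s)\n", names(x$fixation)[i],
                x$fixation[i],
                format(x$pvals[names(x$fixation)[i]], digits = 3)))
  invisible(x)
}

#' Pairwise PhiST between demes
#'
#' Distance-based fixation index from the AMOVA framework for every pair
#' of demes, with significance from permutations of individuals between
#' the two demes and sequential-Bonferroni (Holm) flags at family alpha.
#' Negative estimates are retained. Demes with fewer than 2 individuals
#' are excluded with a warning.
#'
#' @param a an `hd_alignment`.
#' @param n_perm permutations per pair.
#' @param seed integer seed.
#' @param alpha family-wise significance level for the Holm correction.
#' @return an `hd_phist` list: `demes`, `phist` (symmetric matrix),
#'   `pvals`, `significant` (logical matrix), `alpha_initial`.
#' @export
pairwise_phist <- function(a, n_perm = 10000, seed = 1, alpha = 0.05) {
  d2 <- pairwise_diff_matrix(a)
  deme <- factor(unname(a$deme_of[a$ids]))
  sizes <- table(deme)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    warning("excluding demes with <2 individuals: ",
            paste(small, collapse = ", "))
  }
  demes <- names(sizes)[sizes >= 2L]
  if (length(demes) < 2L) stop("need at least 2 demes with n >= 2", call. = FALSE)
  k <- length(demes)
  phist <- matrix(0, k, k, dimnames = list(demes, demes))
  pvals <- matrix(NA_real_, k, k, dimnames = list(demes, demes))
  rng <- local_rng(seed)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      ix <- which(deme %in% c(demes[i], demes[j]))
      sub_d2 <- d2[ix, ix, drop = FALSE]
      lab <- droplevels(deme[ix])
      obs <- amova_one_level(sub_d2, lab)$fixation["F_ST"]
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        st <- amova_one_level(sub_d2, sample(lab))$fixation["F_ST"]
        if (!is.na(st) && !is.na(obs) && st >= obs) cnt <- cnt + 1L
      }
      phist[i, j] <- phist[j, i] <- obs
      pvals[i, j] <- pvals[j, i] <- if (is.na(obs)) NA_real_ else cnt / n_perm
    }
  }
  rng$restore()
  pv <- pvals[upper.tri(pvals)]
  sb <- sequential_bonferroni(pv, alpha = alpha)
  sig <- matrix(NA, k, k, dimnames = list(demes, demes))
  sig[upper.tri(sig)] <- sb$flags
  sig[lower.tri(sig)] <- t(sig)[lower.tri(sig)]
  structure(list(demes = demes, phist = phist, pvals = pvals,
                 significant = sig, alpha_initial = sb$thresholds[1]),
            class = "hd_phist")
}

#' @export
print.hd_phist <- function(x, ...) {
  cat(sprintf("Pairwise PhiST (%d demes); initial Holm alpha = %.4f\n",
              length(x$demes), x$alpha_initial))
  print(round(x$phist, 3))
  invisible(x)
}

#' Sequential Bonferroni (Holm) correction
#'
#' Step-down procedure: p-values are sorted ascending and p_(i) is compared
#' with alpha / (k - i + 1); testing stops at the first failure. The
#' initial threshold is alpha / k.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error rate.
#' @return list with `flags` (logical, in input order) and `thresholds`
#'   (in the sorted testing order).
#' @export
sequential_bonferroni <- function(pvals, alpha = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  k <- length(pvals)
  ord <- order(pvals)
  thresholds <- alpha / (k - seq_len(k) + 1)
  flags_sorted <- logical(k)
  for (i in seq_len(k)) {
    if (!is.na(pvals[ord[i]]) && pvals[ord[i]] <= thresholds[i]) {
      flags_sorted[i] <- TRUE
    } else break
  }
  flags <- logical(k)
  flags[ord] <- flags_sorted
  list(flags = flags, thresholds = thresholds)
}

#' Write the lower-triangle PhiST matrix as TSV
#' @param x an `hd_phist`
#' @param path output path
#' @return invisibly, the path
#' @export
write_phist_table <- function(x, path) {
  k <- length(x$demes)
  m <- matrix("", k, k, dimnames = list(x$demes, x$demes))
  diag(m) <- "-"
  for (i in seq_len(k)) for (j in seq_len(k)) if (i > j)
    m[i, j] <- sprintf("%.3f", x$phist[i, j])
  d <- data.frame(Pop = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an AMOVA table as TSV
#' @param x an `hd_amova`
#' @param path output path
#' @return invisibly, the path
#' @export
write_amova_table <- function(x, path) {
  strata <- names(x$ss)
  fix_of <- c(among_groups = "F_CT", among_populations = "F_SC",
              within_populations = "F_ST")
  if (x$design == "one-level")
    fix_of <- c(among_populations = "F_ST", within_populations = NA)
  rows <- lapply(seq_along(strata), function(i) {
    s <- strata[i]
    fx <- fix_of[[s]]
    data.frame(source = s, ss = round(x$ss[[s]], 1), df = x$df[[s]],
               variance = round(x$var_components[[i]], 3),
               pct = round(x$pct_variation[[i]], 2),
               fixation_index = if (!is.na(fx)) fx else "",
               value = if (!is.na(fx)) round(x$fixation[[fx]], 3) else NA,
               P = if (!is.na(fx) && fx %in% names(x$pvals))
                 x$pvals[[fx]] else NA)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
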
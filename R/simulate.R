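# Structured-coalescent simulator.
#
# Time is measured in pairwise mutational units: a pair of lineages
# separated for time t accumulates Poisson(t) differences, so each lineage
# mutates at rate 1/2 per unit, two lineages in a deme of mutation-scaled
# size theta coalesce at rate 1/theta, and a lineage migrates at rate
# M/(2 theta) when the scaled migration rate is M = 2Nm. Deme splits or
# expansion onsets supplied in coalescent units of N generations convert
# as 1 N-generation unit = theta mutational units.

new_tree_builder <- function(n) {
  env <- new.env()
  env$n_tips <- n
  env$times <- c(rep(0, n))        # node times, tips first
  env$edges <- matrix(numeric(0), ncol = 3,
                      dimnames = list(NULL, c("parent", "child", "length")))
  env$next_node <- n + 1L
  env
}

tb_coalesce <- function(env, a, b, t) {
  p <- env$next_node
  env$next_node <- p + 1L
  env$times <- c(env$times, t)
  env$edges <- rbind(env$edges,
                     c(p, a, t - env$times[a]),
                     c(p, b, t - env$times[b]))
  p
}

tb_finish <- function(env) {
  n_nodes <- env$next_node - 1L
  tip_desc <- vector("list", n_nodes)
  for (i in seq_len(env$n_tips)) tip_desc[[i]] <- i
  ord <- order(env$edges[, "parent"])  # children created before parents
  for (e in ord) {
    p <- env$edges[e, "parent"]; ch <- env$edges[e, "child"]
    tip_desc[[p]] <- c(tip_desc[[p]], tip_desc[[ch]])
  }
  list(edges = env$edges, times = env$times, n_tips = env$n_tips,
       n_nodes = n_nodes, tip_desc = tip_desc,
       tmrca = max(env$times))
}

# Constant-rate single-population coalescent; rate_fn(k) gives the total
# coalescence rate with k lineages.
sim_coalescent_tree <- function(n, rate_fn) {
  tb <- new_tree_builder(n)
  active <- seq_len(n)
  t <- 0
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + rexp(1, rate_fn(k))
    pair <- sample.int(k, 2L)
    p <- tb_coalesce(tb, active[pair[1]], active[pair[2]], t)
    active <- c(active[-pair], p)
  }
  tb_finish(tb)
}

# Piecewise-constant population size: thetas[i] applies on
# [breaks[i-1], breaks[i]) with breaks of length(thetas) - 1.
sim_tree_piecewise <- function(n, thetas, breaks) {
  tb <- new_tree_builder(n)
  active <- seq_len(n)
  t <- 0
  epoch <- 1L
  while (length(active) > 1L) {
    k <- length(active)
    repeat {
      th <- thetas[epoch]
      rate <- if (th > 0) k * (k - 1) / 2 / th else Inf
      nxt <- if (epoch <= length(breaks)) breaks[epoch] else Inf
      if (!is.finite(rate)) { w <- 0 } else w <- rexp(1, rate)
      if (t + w >= nxt) { t <- nxt; epoch <- epoch + 1L } else { t <- t + w; break }
    }
    pair <- sample.int(k, 2L)
    p <- tb_coalesce(tb, active[pair[1]], active[pair[2]], t)
    active <- c(active[-pair], p)
  }
  tb_finish(tb)
}

# Structured coalescent over demes. deme0: sampling deme per lineage.
# mig[i, j]: per-lineage migration rate from deme i to deme j (mutational
# time). merge_time: all lineages collapse into deme 1 (migration stops).
# infinite_island: migrating lineages move to an inert "outside" state
# (deme 0) where they cannot coalesce or migrate until merge_time.
sim_tree_structured <- function(deme0, theta, mig = NULL, merge_time = Inf,
                                infinite_island = FALSE, out_rate = 0) {
  n <- length(deme0)
  tb <- new_tree_builder(n)
  active <- seq_len(n)
  deme <- deme0
  t <- 0
  merged <- FALSE
  repeat {
    if (length(active) == 1L) break
    if (!merged && t >= merge_time) {
      deme <- rep(1L, length(active))
      merged <- TRUE
    }
    k_by <- table(deme[deme > 0])
    coal_rates <- vapply(names(k_by), function(d) {
      k <- k_by[[d]]
      if (theta > 0) k * (k - 1) / 2 / theta else Inf
    }, 0)
    if (any(is.infinite(coal_rates))) {
      d_star <- names(coal_rates)[which(is.infinite(coal_rates))[1]]
      ix <- which(deme == as.integer(d_star))
      pair <- ix[sample.int(length(ix), 2L)]
      p <- tb_coalesce(tb, active[pair[1]], active[pair[2]], t)
      keep <- setdiff(seq_along(active), pair)
      active <- c(active[keep], p); deme <- c(deme[keep], as.integer(d_star))
      next
    }
    mig_rates <- if (merged) 0 else if (infinite_island) {
      ifelse(deme > 0, out_rate, 0)
    } else if (!is.null(mig)) {
      rowSums(mig)[deme]
    } else 0
    total <- sum(coal_rates) + sum(mig_rates)
    if (total <= 0) {
      if (is.finite(merge_time) && !merged) { t <- merge_time; next }
      stop("structured coalescent cannot proceed (no events possible)",
           call. = FALSE)
    }
    w <- rexp(1, total)
    if (!merged && t + w >= merge_time) { t <- merge_time; next }
    t <- t + w
    if (runif(1) < sum(coal_rates) / total) {
      d_star <- sample(names(coal_rates), 1L, prob = coal_rates)
      ix <- which(deme == as.integer(d_star))
      pair <- ix[sample.int(length(ix), 2L)]
      p <- tb_coalesce(tb, active[pair[1]], active[pair[2]], t)
      keep <- setdiff(seq_along(active), pair)
      active <- c(active[keep], p); deme <- c(deme[keep], as.integer(d_star))
    } else {
      pr <- mig_rates / sum(mig_rates)
      li <- sample(seq_along(active), 1L, prob = pr)
      if (infinite_island) {
        deme[li] <- 0L
      } else {
        deme[li] <- sample(seq_len(ncol(mig)), 1L, prob = mig[deme[li], ])
      }
    }
  }
  tb_finish(tb)
}

default_base_freqs <- c(A = 0.33, C = 0.17, G = 0.19, T = 0.31)

mutate_infinite_sites <- function(tree, L, base_freqs = default_base_freqs) {
  anc <- sample(VALID_BASES, L, replace = TRUE, prob = base_freqs)
  seqs <- matrix(rep(anc, tree$n_tips), nrow = tree$n_tips, byrow = TRUE)
  nmut <- rpois(nrow(tree$edges), tree$edges[, "length"] / 2)
  total <- sum(nmut)
  if (total > L)
    stop("more mutations than sites: increase L or reduce theta/tau",
         call. = FALSE)
  sites <- sample.int(L, total)
  s_ix <- 0L
  for (e in seq_len(nrow(tree$edges))) {
    if (nmut[e] == 0L) next
    tips <- tree$tip_desc[[tree$edges[e, "child"]]]
    for (m in seq_len(nmut[e])) {
      s_ix <- s_ix + 1L
      s <- sites[s_ix]
      newb <- sample(setdiff(VALID_BASES, anc[s]), 1L)
      seqs[tips, s] <- newb
    }
  }
  seqs
}

hky_transition <- function(t, kappa, freqs) {
  # rate matrix normalised to one expected substitution per unit time
  Q <- matrix(0, 4, 4, dimnames = list(VALID_BASES, VALID_BASES))
  transitions <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  for (i in VALID_BASES) for (j in VALID_BASES) if (i != j) {
    k <- if (any(transitions[, 1] == i & transitions[, 2] == j)) kappa else 1
    Q[i, j] <- k * freqs[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  eig <- eigen(Q)
  V <- eig$vectors
  Vi <- solve(V)
  list(P = function(len) Re(V %*% diag(exp(eig$values * len)) %*% Vi), Q = Q)
}

mutate_hky <- function(tree, L, kappa = 4, base_freqs = default_base_freqs) {
  hk <- hky_transition(0, kappa, base_freqs)
  states <- matrix(NA_integer_, tree$n_nodes, L)
  root <- tree$n_nodes
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = base_freqs)
  ord <- order(tree$edges[, "parent"], decreasing = TRUE)
  for (e in ord) {
    p <- tree$edges[e, "parent"]; ch <- tree$edges[e, "child"]
    # per-site substitutions: branch carries length/2 per-sequence mutations
    P <- hk$P(tree$edges[e, "length"] / (2 * L))
    P <- pmax(P, 0); P <- P / rowSums(P)
    ps <- states[p, ]
    u <- runif(L)
    cp <- t(apply(P, 1, cumsum))
    states[ch, ] <- max.col(outer(u, rep(1, 4)) <= cp[ps, , drop = FALSE],
                            ties.method = "first")
  }
  matrix(VALID_BASES[states[seq_len(tree$n_tips), ]], nrow = tree$n_tips)
}

#' Simulate an alignment under a coalescent scenario
#'
#' Scenarios: `panmictic` (constant size), `sudden_expansion` (size theta0
#' switching to theta1 at tau mutational units before present), `island`
#' (finite island model), `stepping_stone` (1-D chain), `im_pair` (two
#' demes splitting T N-generation units ago with symmetric migration M)
#' and `spatial_expansion` (focal deme of an infinite-island world that
#' expanded tau mutational units ago; lineages that scatter out of the
#' focal deme stay apart until the expansion time).
#'
#' @param scenario one of the six scenario names.
#' @param n sample size (single deme scenarios) or vector of per-deme
#'   sample sizes.
#' @param L alignment length in sites.
#' @param theta mutation-scaled deme size (panmictic/island/
#'   stepping_stone/im_pair/spatial_expansion).
#' @param theta0,theta1,tau sudden-expansion parameters (also `theta`,
#'   `M`, `tau` for `spatial_expansion`).
#' @param M scaled migration rate 2Nm.
#' @param T_split im_pair split time in coalescent units of N generations.
#' @param n_demes number of demes for island/stepping_stone.
#' @param mutation `"infinite_sites"` or `"hky"`.
#' @param kappa HKY transition/transversion rate ratio.
#' @param base_freqs base frequencies (study-like A+T-rich default).
#' @param seed integer seed (`NULL` continues the caller's RNG stream).
#' @return list with `alignment` (an `hd_alignment`), `truth` (generating
#'   parameters) and `tree`.
#' @export
simulate_coalescent <- function(scenario = c("panmictic", "sudden_expansion",
                                             "island", "stepping_stone",
                                             "im_pair", "spatial_expansion"),
                                n = 20, L = 1000, theta = 2, theta0 = 0.1,
                                theta1 = 10, tau = 5, M = 1, T_split = 1,
                                n_demes = 2, mutation = c("infinite_sites", "hky"),
                                kappa = 4, base_freqs = default_base_freqs,
                                seed = NULL) {
  scenario <- match.arg(scenario)
  mutation <- match.arg(mutation)
  rng <- if (!is.null(seed)) local_rng(seed) else NULL
  zero_theta <- switch(scenario,
    panmictic = , island = , stepping_stone = , im_pair = ,
    spatial_expansion = theta <= 0,
    sudden_expansion = theta0 <= 0 && theta1 <= 0)
  tree <- if (zero_theta) {
    # no variation possible: star tree of zero depth
    tb <- new_tree_builder(sum(n))
    active <- seq_len(sum(n))
    while (length(active) > 1L) {
      p <- tb_coalesce(tb, active[1], active[2], 0)
      active <- c(active[-c(1, 2)], p)
    }
    tb_finish(tb)
  } else switch(scenario,
    panmictic = {
      stopifnot(length(n) == 1L)
      sim_coalescent_tree(n, function(k) k * (k - 1) / 2 / theta)
    },
    sudden_expansion = {
      stopifnot(length(n) == 1L)
      sim_tree_piecewise(n, c(theta1, theta0), tau)
    },
    island = {
      if (n_demes < 2L) stop("island model needs >= 2 demes", call. = FALSE)
      sizes <- if (length(n) == 1L) rep(n, n_demes) else n
      deme0 <- rep(seq_len(n_demes), sizes)
      mig <- matrix(M / (2 * theta) / (n_demes - 1), n_demes, n_demes)
      diag(mig) <- 0
      sim_tree_structured(deme0, theta, mig)
    },
    stepping_stone = {
      if (n_demes < 2L) stop("stepping stone needs >= 2 demes", call. = FALSE)
      sizes <- if (length(n) == 1L) rep(n, n_demes) else n
      deme0 <- rep(seq_len(n_demes), sizes)
      mig <- matrix(0, n_demes, n_demes)
      for (i in seq_len(n_demes)) {
        nb <- c(i - 1, i + 1); nb <- nb[nb >= 1 & nb <= n_demes]
        mig[i, nb] <- M / (2 * theta) / length(nb)
      }
      sim_tree_structured(deme0, theta, mig)
    },
    im_pair = {
      sizes <- if (length(n) == 1L) rep(n, 2) else n
      stopifnot(length(sizes) == 2L)
      deme0 <- rep(1:2, sizes)
      mig <- matrix(c(0, M / (2 * theta), M / (2 * theta), 0), 2, 2)
      sim_tree_structured(deme0, theta, mig, merge_time = T_split * theta)
    },
    spatial_expansion = {
      stopifnot(length(n) == 1L)
      sim_tree_structured(rep(1L, n), theta, merge_time = tau,
                          infinite_island = TRUE,
                          out_rate = M / (2 * theta))
    })
  seqs <- if (mutation == "infinite_sites") mutate_infinite_sites(tree, L, base_freqs)
          else mutate_hky(tree, L, kappa, base_freqs)
  deme0 <- switch(scenario,
    island = , stepping_stone = rep(seq_len(n_demes),
                                    if (length(n) == 1L) rep(n, n_demes) else n),
    im_pair = rep(1:2, if (length(n) == 1L) rep(n, 2) else n),
    rep(1L, nrow(seqs)))
  ids <- sprintf("ind%03d", seq_len(nrow(seqs)))
  rownames(seqs) <- ids
  deme_of <- setNames(paste0("deme", deme0), ids)
  aln <- hd_alignment(seqs, deme_of)
  if (!is.null(rng)) rng$restore()
  truth <- list(scenario = scenario, n = n, L = L, theta = theta,
                theta0 = theta0, theta1 = theta1, tau = tau, M = M,
                T_split = T_split, n_demes = n_demes, mutation = mutation,
                tmrca = tree$tmrca)
  list(alignment = aln, truth = truth, tree = tree)
}

# ---------------------------------------------------------------------------
# Study-like fixture: 7 demes in 3 divergent haplogroups, 93 individuals,
# 27 planted haplotypes with fixed per-deme counts, two concatenated
# partitions (560 + 465 sites) and A+T-rich composition.

study_design <- function() {
  list(
    demes = data.frame(
      deme = c("ALB", "KO3", "KO4", "AVE", "CIR", "FO", "CP"),
      n = c(16L, 10L, 14L, 20L, 13L, 10L, 10L),
      lat = c(40.944, 39.616, 39.628, 40.050, 41.348, 41.441, 41.705),
      lon = c(19.866, 19.820, 19.831, 16.245, 13.047, 12.732, 12.396),
      group = c("AlbSItaly", "Corfu", "Corfu", "AlbSItaly",
                "CItaly", "CItaly", "CItaly")),
    # haplotype x deme counts (27 haplotypes over 93 individuals)
    counts = {
      demes <- c("ALB", "KO3", "KO4", "AVE", "CIR", "FO", "CP")
      m <- matrix(0L, 27, 7, dimnames = list(paste0("H", 1:27), demes))
      m["H1", "ALB"] <- 1; m["H2", "ALB"] <- 9; m["H3", "ALB"] <- 4
      m["H4", "ALB"] <- 1; m["H5", "ALB"] <- 1
      m["H6", "AVE"] <- 1; m["H7", "AVE"] <- 3; m["H8", "AVE"] <- 16
      m["H9", "CIR"] <- 1; m["H10", "CIR"] <- 1; m["H11", "CIR"] <- 4
      m["H12", "CIR"] <- 6; m["H13", "CIR"] <- 1
      m["H14", "CP"] <- 1; m["H15", "CP"] <- 9
      m["H16", "FO"] <- 1; m["H17", "FO"] <- 6; m["H18", "FO"] <- 2
      m["H19", "FO"] <- 1
      m["H20", "KO3"] <- 1; m["H21", "KO3"] <- 1; m["H21", "KO4"] <- 4
      m["H22", "KO3"] <- 5; m["H22", "KO4"] <- 8
      m["H23", "KO3"] <- 1; m["H24", "KO3"] <- 1; m["H25", "KO3"] <- 1
      m["H26", "KO4"] <- 1; m["H27", "KO4"] <- 1
      m
    },
    # mutational steps of each haplotype away from its group founder
    # (every step hits a fresh site, so planted distances are exact);
    # group founders: CItaly = ancestral sequence, Corfu = +25 steps,
    # AlbSItaly = +20 steps. H9 and H20 are the far-out haplotypes.
    steps = c(H1 = 1, H2 = 0, H3 = 1, H4 = 2, H5 = 1, H6 = 2, H7 = 3,
              H8 = 4, H9 = 20, H10 = 1, H11 = 2, H12 = 1, H13 = 3,
              H14 = 5, H15 = 0, H16 = 2, H17 = 1, H18 = 2, H19 = 3,
              H20 = 16, H21 = 1, H22 = 0, H23 = 1, H24 = 2, H25 = 1,
              H26 = 2, H27 = 1),
    founder_steps = c(CItaly = 0, AlbSItaly = 20, Corfu = 25),
    group_of_hap = c(rep("AlbSItaly", 8), rep("CItaly", 11),
                     rep("Corfu", 8)))
}

#' Deterministic study-like synthetic data set
#'
#' Builds a 93-individual, 1,025-site alignment (two partitions of 560 and
#' 465 sites) over 7 demes in 3 divergent haplogroups, with 27 planted
#' haplotypes at fixed per-deme counts, A+T-rich base composition,
#' between-group divergence far above the 95% parsimony connection limit
#' and two far-out haplotypes (16-20 steps from their own group). Identical
#' seeds give identical alignments.
#'
#' @param seed integer seed.
#' @return list with `alignment` (an `hd_alignment` with groups and
#'   coordinates attached) and `truth` (planted haplotypes and design).
#' @export
make_study_fixture <- function(seed = 1) {
  rng <- local_rng(seed)
  on.exit(rng$restore())
  des <- study_design()
  L <- 1025L
  anc <- sample(VALID_BASES, L, replace = TRUE, prob = default_base_freqs)
  total_steps <- sum(des$founder_steps) + sum(des$steps)
  sites <- sample.int(L, total_steps)
  s_ix <- 0L
  take_sites <- function(k) {
    if (k == 0L) return(integer(0))
    out <- sites[s_ix + seq_len(k)]
    s_ix <<- s_ix + k
    out
  }
  mutate_at <- function(seq, at) {
    for (s in at) seq[s] <- sample(setdiff(VALID_BASES, seq[s]), 1L)
    seq
  }
  founders <- list()
  for (g in names(des$founder_steps))
    founders[[g]] <- mutate_at(anc, take_sites(des$founder_steps[[g]]))
  hap_seqs <- list()
  for (h in rownames(des$counts)) {
    g <- des$group_of_hap[match(h, rownames(des$counts))]
    hap_seqs[[h]] <- mutate_at(founders[[g]], take_sites(des$steps[[h]]))
  }
  ids <- character(0); deme_of <- character(0)
  seqs <- NULL
  counter <- 0L
  # demes ordered so that haplotypes first appear in H1..H27 label order
  # (collapse_haplotypes numbers by first appearance)
  for (dm in c("ALB", "AVE", "CIR", "CP", "FO", "KO3", "KO4")) {
    for (h in rownames(des$counts)) {
      k <- des$counts[h, dm]
      if (k == 0L) next
      for (r in seq_len(k)) {
        counter <- counter + 1L
        id <- sprintf("%s_%02d", dm, sum(deme_of == dm) + 1L)
        ids <- c(ids, id)
        deme_of <- c(deme_of, setNames(dm, id))
        seqs <- rbind(seqs, hap_seqs[[h]])
      }
    }
  }
  rownames(seqs) <- ids
  aln <- hd_alignment(seqs, deme_of,
                      partitions = list(COI = c(1L, 560L), S16 = c(561L, 1025L)),
                      group_of = setNames(des$demes$group, des$demes$deme),
                      coords = des$demes[, c("deme", "lat", "lon")])
  list(alignment = aln,
       truth = list(counts = des$counts, steps = des$steps,
                    founder_steps = des$founder_steps,
                    hap_seqs = vapply(hap_seqs, paste, "", collapse = ""),
                    design = des$demes))
}

#' Write a simulated data set to disk (FASTA + popmap + coords + truth)
#' @param sim result of [simulate_coalescent()] or [make_study_fixture()]
#' @param dir output directory (created if needed)
#' @param prefix file name prefix
#' @return invisibly, the paths written
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  pm <- file.path(dir, paste0(prefix, "_popmap.csv"))
  co <- if (!is.null(sim$alignment$coords))
    file.path(dir, paste0(prefix, "_coords.csv")) else NULL
  write_alignment(sim$alignment, fa, pm, co)
  tj <- file.path(dir, paste0(prefix, "_truth.json"))
  truth <- sim$truth
  truth$counts <- NULL; truth$hap_seqs <- NULL; truth$design <- NULL
  jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
  invisible(c(fa, pm, co, tj))
}
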
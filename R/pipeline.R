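#' Default pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]; can be written/read as
#' YAML. Stage toggles, permutation/bootstrap counts, distance-class
#' presets, the rate model and IM priors are all explicit so a run is fully
#' reproducible from its config and global seed.
#'
#' @param fasta,popmap,coords input paths (coords optional).
#' @param partitions named list of `c(first, last)` column ranges.
#' @param out_dir output directory.
#' @param seed global seed; each stage derives its own stream from it.
#' @param stages character vector of stages to run.
#' @param n_perm,n_boot permutation and bootstrap counts.
#' @param class_size_km spatial distance-class width preset.
#' @param u_seq,generation_years rate model.
#' @param im list with `pair` (two deme labels) and prior bounds
#'   `theta_max`, `M_max`, `T_max`, plus `steps`, `n_chains`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(fasta, popmap, coords = NULL,
                            partitions = NULL, out_dir = "haplodem_out",
                            seed = 1,
                            stages = c("seqio", "diversity", "structure",
                                       "network", "spatial", "mismatch",
                                       "im"),
                            n_perm = 10000, n_boot = 1000,
                            class_size_km = 50, u_seq = 2e-5,
                            generation_years = 1, im = NULL) {
  structure(list(fasta = fasta, popmap = popmap, coords = coords,
                 partitions = partitions, out_dir = out_dir, seed = seed,
                 stages = stages, n_perm = n_perm, n_boot = n_boot,
                 class_size_km = class_size_km, u_seq = u_seq,
                 generation_years = generation_years, im = im),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (length(y$partitions) > 0L) {
    y$partitions <- lapply(y$partitions, function(p) as.integer(unlist(p)))
  } else {
    y$partitions <- NULL
  }
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (seqio, diversity, structure,
#' network, spatial, mismatch, im), writing one TSV per report plus a JSON
#' manifest with versions, seeds and per-stage status. A failing stage is
#' recorded in the manifest and does not remove outputs already written.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "haplodem",
                   version = as.character(utils::packageVersion("haplodem")),
                   seed = cfg$seed, started = format(Sys.time()),
                   stages = list())
  aln <- read_alignment(cfg$fasta, cfg$popmap, partitions = cfg$partitions,
                        coords_path = cfg$coords)
  haps <- NULL
  run_stage <- function(name, fn) {
    if (!(name %in% cfg$stages)) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    res <- tryCatch({
      fn()
      list(status = "ok")
    }, error = function(e) list(status = "error",
                                message = conditionMessage(e)))
    res$seconds <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    manifest$stages[[name]] <<- res
  }
  run_stage("seqio", function() {
    haps <<- collapse_haplotypes(aln)
    write_haplotype_table(haps, file.path(cfg$out_dir, "haplotypes.tsv"))
    st <- site_statistics(aln)
    write.table(st$per_partition,
                file.path(cfg$out_dir, "site_statistics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    chi <- base_homogeneity_chi2(aln)
    writeLines(sprintf("chi2\t%.4f\ndf\t%d\np\t%.4g", chi$chi2, chi$df,
                       chi$p),
               file.path(cfg$out_dir, "base_homogeneity.tsv"))
  })
  run_stage("diversity", function() {
    if (is.null(haps)) haps <<- collapse_haplotypes(aln)
    write_diversity_table(diversity_table(aln, haps),
                          file.path(cfg$out_dir, "diversity.tsv"))
  })
  run_stage("structure", function() {
    ph <- pairwise_phist(aln, n_perm = cfg$n_perm,
                         seed = stage_seed(cfg$seed, "structure"))
    write_phist_table(ph, file.path(cfg$out_dir, "phist.tsv"))
    am1 <- amova(aln, grouping = NULL, n_perm = cfg$n_perm,
                 seed = stage_seed(cfg$seed, "structure"))
    write_amova_table(am1, file.path(cfg$out_dir, "amova_one_level.tsv"))
    if (!is.null(aln$group_of)) {
      am2 <- amova(aln, n_perm = cfg$n_perm,
                   seed = stage_seed(cfg$seed, "structure"))
      write_amova_table(am2, file.path(cfg$out_dir, "amova_two_level.tsv"))
    }
  })
  run_stage("network", function() {
    if (is.null(haps)) haps <<- collapse_haplotypes(aln)
    nw <- build_network(haps)
    write_network(nw, file.path(cfg$out_dir, "network_nodes.tsv"),
                  file.path(cfg$out_dir, "network_edges.tsv"))
  })
  run_stage("spatial", function() {
    if (is.null(aln$coords)) stop("spatial stage needs coordinates")
    geo <- individual_geo_distances(aln)
    gd <- pairwise_diff_matrix(aln)
    cg <- spatial_autocorrelogram(gd, geo, cfg$class_size_km,
                                  n_perm = min(cfg$n_perm, 999),
                                  n_boot = cfg$n_boot,
                                  seed = stage_seed(cfg$seed, "spatial"))
    write_correlogram(cg, file.path(cfg$out_dir, "correlogram.tsv"))
    ph <- pairwise_phist(aln, n_perm = 0, seed = 1)
    dd <- geo_distances(aln$coords)
    dd <- dd[ph$demes, ph$demes]
    mt <- mantel_test(ph$phist, dd, n_perm = cfg$n_perm,
                      seed = stage_seed(cfg$seed, "spatial"))
    writeLines(sprintf("R\t%.4f\np\t%.4f", mt$R, mt$p),
               file.path(cfg$out_dir, "mantel.tsv"))
  })
  run_stage("mismatch", function() {
    rm_ <- rate_model(cfg$u_seq, cfg$generation_years)
    rep_ <- mismatch_report(aln, rm = rm_, n_boot = cfg$n_boot,
                            seed = stage_seed(cfg$seed, "mismatch"))
    write_mismatch_report(rep_, file.path(cfg$out_dir, "mismatch.tsv"))
    fs <- lapply(unique(unname(aln$deme_of)), function(d) {
      ids <- aln$ids[aln$deme_of[aln$ids] == d]
      if (length(ids) < 3L) return(NULL)
      r <- fu_fs(aln, d, n_sim = cfg$n_boot,
                 seed = stage_seed(cfg$seed, "mismatch"))
      data.frame(deme = d, FS = r$FS, p = r$p, k = r$k, pi = r$pi)
    })
    fs <- do.call(rbind, fs)
    write.table(fs, file.path(cfg$out_dir, "fu_fs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  run_stage("im", function() {
    if (is.null(cfg$im)) stop("im stage needs cfg$im (pair and priors)")
    icfg <- im_config(theta_max = cfg$im$theta_max, M_max = cfg$im$M_max,
                      T_max = cfg$im$T_max,
                      steps = if (!is.null(cfg$im$steps)) cfg$im$steps else 200000,
                      n_chains = if (!is.null(cfg$im$n_chains)) cfg$im$n_chains else 3,
                      seed = stage_seed(cfg$seed, "im"))
    post <- run_mdiv(aln, cfg$im$pair, icfg)
    write_im_results(post, cfg$out_dir,
                     rm = rate_model(cfg$u_seq, cfg$generation_years))
  })
  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
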
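# End-to-end pipeline: sample -> cluster -> classify -> tables.

#' Pipeline configuration
#'
#' Validates and assembles the configuration for [run_pipeline()].
#' Unknown entries are rejected.
#'
#' @param specs Helix definitions (named list of [helix_spec()]), or a
#'   path to a helix config file.
#' @param restraints A [restraint_set()].
#' @param mc An [mc_config()] (its seed is overridden by `seed`).
#' @param cluster_cutoff RMSD clustering cutoff, Angstrom.
#' @param top_k Size of the top-scoring subset in the arrangement table.
#' @param seed Global integer seed (mandatory).
#' @param ... Unknown arguments; any use is an error.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(specs = btl_helix_specs(),
                            restraints = restraint_set(),
                            mc = NULL, cluster_cutoff = 2, top_k = 100,
                            seed, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown pipeline config entr",
         if (length(extra) > 1) "ies: " else "y: ",
         paste(names(extra), collapse = ", "))
  if (missing(seed)) stop("a global seed is mandatory")
  if (is.character(specs)) specs <- read_helix_config(specs)
  if (is.null(mc)) mc <- mc_config(n_steps = 5000, seed = seed)
  mc$seed <- as.integer(seed)
  structure(list(specs = specs, restraints = restraints, mc = mc,
                 cluster_cutoff = cluster_cutoff, top_k = top_k,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the bundle-assembly pipeline
#'
#' Monte Carlo sampling under the restraint set, RMSD clustering of the
#' recorded ensemble, arrangement classification of the cluster
#' centroids, the arrangement distribution table, and per-arrangement
#' distance statistics. When `out_dir` is given, all artifacts are
#' written there: the sampled ensemble and centroids as multi-model
#' PDB, the cluster and arrangement tables and distance statistics as
#' CSV, and a JSON run report with the resolved configuration, seed,
#' package version and per-stage timings.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return Invisible list with `ensemble`, `clustered`, `table`,
#'   `distances`, `report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  initial <- build_bundle(config$specs)
  ens <- run_mc(initial, config$restraints, config$mc)
  timings["sample"] <- toc(t0)

  t0 <- tic()
  clustered <- cluster_ensemble(ens, cutoff = config$cluster_cutoff)
  timings["cluster"] <- toc(t0)

  t0 <- tic()
  tab <- arrangement_table(clustered, top_k = config$top_k)
  labels <- classify_ensemble(ens)
  dstats <- tryCatch(distance_stats(ens, labels),
                     error = function(e) NULL)
  timings["classify"] <- toc(t0)

  report <- list(
    package = "tmbundler",
    version = as.character(utils::packageVersion("tmbundler")),
    seed = config$seed,
    n_recorded = nrow(ens$xyz),
    n_clusters = clustered$n_clusters,
    acceptance_rate = ens$acceptance_rate,
    top3_share_all = attr(tab, "top3_share_all"),
    top3_count_top = attr(tab, "top3_count_top"),
    weights = as.list(config$restraints$weights),
    cluster_cutoff = config$cluster_cutoff,
    rmsd_superposed = clustered$superpose,
    top_k = config$top_k,
    mc = list(n_steps = config$mc$n_steps,
              record_stride = config$mc$record_stride,
              n_restarts = config$mc$n_restarts,
              schedule = config$mc$schedule),
    timings_sec = as.list(round(timings, 3)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bundle_pdb(ens, file.path(out_dir, "ensemble.pdb"))
    cent <- ens
    cent$xyz <- ens$xyz[clustered$centroids, , drop = FALSE]
    cent$scores <- clustered$centroid_scores
    cent$transforms <- ens$transforms[clustered$centroids]
    write_bundle_pdb(cent, file.path(out_dir, "centroids.pdb"))
    utils::write.csv(data.frame(member = seq_along(clustered$assignment),
                                cluster = clustered$assignment),
                     file.path(out_dir, "clusters.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(tab),
                     file.path(out_dir, "arrangement_table.csv"),
                     row.names = FALSE)
    if (!is.null(dstats))
      utils::write.csv(dstats, file.path(out_dir, "distance_stats.csv"),
                       row.names = FALSE)
    helix_cfg <- lapply(config$specs, function(s)
      list(name = s$name, sequence = s$sequence, start = s$start_resnum,
           end = s$end_resnum, allowed_axes = s$allowed_axes,
           n_term = s$n_term))
    yaml::write_yaml(list(helices = unname(helix_cfg),
                          seed = config$seed,
                          cluster_cutoff = config$cluster_cutoff,
                          top_k = config$top_k),
                     file.path(out_dir, "resolved_config.yaml"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(list(ensemble = ens, clustered = clustered, table = tab,
                 distances = dstats, report = report))
}
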
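#' Assemble a pipeline configuration
#'
#' Bundles the stage configurations for a full run. A single global seed
#' fans out to fixed per-stage child seeds so each stage is individually
#' reproducible.
#'
#' @param seed global integer seed.
#' @param cohort a [cohort_sim_config()] (its seed is overridden by the
#'   cohort child seed).
#' @param spatial a [spatial_sim_config()] (seed overridden likewise).
#' @param qc a [qc_config()].
#' @param panels marker panels.
#' @param tau bipotency threshold.
#' @param k_modules modules to cut from the frequency linkage (default 4).
#' @param k_neighbors spatial neighbours per type (default 4).
#' @param top_n marker genes retained per module (default 250).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = cohort_sim_config(),
                            spatial = spatial_sim_config(),
                            qc = qc_config(),
                            panels = default_marker_panels(),
                            tau = 0.5, k_modules = 4, k_neighbors = 4,
                            top_n = 250) {
  cohort$seed <- child_seed(seed, "cohort")
  spatial$seed <- child_seed(seed, "spatial")
  structure(list(seed = as.integer(seed), cohort = cohort, spatial = spatial,
                 qc = qc, panels = panels, tau = tau, k_modules = k_modules,
                 k_neighbors = k_neighbors, top_n = top_n),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads the scage-level scalar overrides (seed, tau, k_modules,
#' k_neighbors, top_n, and any named field of the cohort, spatial and qc
#' configs) from a YAML file; unspecified fields keep their defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_lpc(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_sim_config, y$cohort %||% list())
  spatial <- do.call(spatial_sim_config, y$spatial %||% list())
  qc <- do.call(qc_config, y$qc %||% list())
  pipeline_config(seed = y$seed %||% 1L, cohort = cohort, spatial = spatial,
                  qc = qc, tau = y$tau %||% 0.5,
                  k_modules = y$k_modules %||% 4,
                  k_neighbors = y$k_neighbors %||% 4,
                  top_n = y$top_n %||% 250)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> qc -> annotate -> modules -> spatial in order,
#' writing every intermediate bundle under `out_dir` (when given) and
#' returning a consolidated report. Identical config + seed gives identical
#' numeric outputs. Any stage error aborts with the stage name; artifacts
#' written so far are preserved.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional output directory for artifacts; `NULL` keeps
#'   everything in memory.
#' @return A list of class `run_report` with one block per stage
#'   (`simulate`, `qc`, `annotate`, `modules`, `spatial`) plus `results`
#'   (the in-memory stage outputs).
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  report <- list(seed = cfg$seed,
                 version = as.character(utils::packageVersion("lpcmod")))
  results <- list()
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop_lpc(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- simulate ------------------------------------------------------------
  sim <- stage("simulate", function() {
    list(cohort = simulate_cohort(cfg$cohort), map = simulate_spatial(cfg$spatial))
  })
  results$sim <- sim
  report$simulate <- list(n_cells = nrow(sim$cohort$expr$counts),
                          n_genes = ncol(sim$cohort$expr$counts),
                          n_individuals = cfg$cohort$n_individuals,
                          n_spatial_cells = nrow(sim$map))
  if (!is.null(out_dir)) {
    write_expression_bundle(sim$cohort$expr, file.path(out_dir, "cohort"))
    write_spatial_map(sim$map, file.path(out_dir, "spatial_cells.csv"))
  }

  # --- qc ------------------------------------------------------------------
  qc <- stage("qc", function() qc_filter(sim$cohort$expr, cfg$qc))
  results$qc <- qc
  report$qc <- list(cells_in = qc$report$n_cells_in,
                    cells_out = qc$report$n_cells_out,
                    genes_out = qc$report$n_genes_out,
                    removed_by_rule = qc$report$removed_by_rule)
  if (!is.null(out_dir)) {
    write_expression_bundle(qc$expr, file.path(out_dir, "qc"))
    jsonlite::write_json(report$qc, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE)
  }

  # --- annotate ------------------------------------------------------------
  ann <- stage("annotate", function() {
    a <- annotate_cohort(qc$expr, cfg$panels, tau = cfg$tau)
    props <- lpc_proportions(a$cell_type, qc$expr$cell_meta$individual)
    list(ann = a, props = props)
  })
  results$annotate <- ann
  report$annotate <- list(
    cluster_types = as.list(ann$ann$cluster_type),
    lpc_clusters = names(ann$ann$lpc_flags)[ann$ann$lpc_flags],
    lpc_prop_mean = ann$props$mean, lpc_prop_sd = ann$props$sd,
    n_individuals = ann$props$n)
  if (!is.null(out_dir)) {
    utils::write.csv(ann$props$per_individual,
                     file.path(out_dir, "lpc_proportions.csv"), row.names = FALSE)
  }

  # --- modules -------------------------------------------------------------
  modres <- stage("modules", function() {
    ft <- cluster_frequency_table(qc$expr$cell_meta$cluster,
                                  qc$expr$cell_meta$individual)
    fc <- frequency_correlation(ft)
    k <- min(cfg$k_modules, nrow(fc$d))
    tree <- ward_d_linkage(fc$d)
    mods <- cut_modules(tree, k)
    mk <- module_markers(qc$expr, mods, top_n = cfg$top_n)
    list(freq = ft, corr = fc, tree = tree, modules = mods, markers = mk)
  })
  results$modules <- modres
  report$modules <- list(k = length(unique(modres$modules)),
                         assignment = as.list(modres$modules))
  if (!is.null(out_dir)) {
    utils::write.csv(modres$corr$r, file.path(out_dir, "cluster_correlation.csv"))
    utils::write.csv(data.frame(cluster = names(modres$modules),
                                module = modres$modules),
                     file.path(out_dir, "modules.csv"), row.names = FALSE)
    write_linkage_newick(modres$tree, file.path(out_dir, "modules.nwk"))
    if (!is.null(modres$markers$table)) {
      utils::write.csv(modres$markers$table, file.path(out_dir, "module_degs.csv"),
                       row.names = FALSE)
    }
  }

  # --- spatial -------------------------------------------------------------
  sp <- stage("spatial", function() {
    prof <- knn_type_distance_profiles(sim$map, "LPC", k = cfg$k_neighbors)
    rk <- rank_colocalization(prof)
    grp <- cluster_distance_profiles(prof, k_groups = 2)
    lpc_cells <- results$annotate$ann$cell_type == "LPC"
    r <- NA_real_
    if (sum(lpc_cells) >= 2) {
      half <- which(lpc_cells)
      a <- pseudobulk_profile(qc$expr, half[seq_len(floor(length(half) / 2))], "half1")
      b <- pseudobulk_profile(qc$expr, half[-seq_len(floor(length(half) / 2))], "half2")
      r <- pseudobulk_correlation(a, b)
    }
    list(profiles = prof, ranking = rk, groups = grp, split_half_r = r)
  })
  results$spatial <- sp
  report$spatial <- list(ranking = sp$ranking$cell_type,
                         nearest_type = sp$ranking$cell_type[1],
                         split_half_r = sp$split_half_r)
  if (!is.null(out_dir)) {
    utils::write.csv(sp$profiles$profiles,
                     file.path(out_dir, "distance_profiles.csv"))
    utils::write.csv(sp$ranking, file.path(out_dir, "colocalization_ranking.csv"),
                     row.names = FALSE)
  }

  report$wall_clock_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!is.null(out_dir)) {
    jsonlite::write_json(report[setdiff(names(report), "results")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(c(report, list(results = results)), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  cells simulated: %d; after QC: %d\n",
              x$simulate$n_cells, x$qc$cells_out))
  cat(sprintf("  LPC clusters: %s\n",
              paste(x$annotate$lpc_clusters, collapse = ", ")))
  cat(sprintf("  LPC proportion: %.2f%% +/- %.2f%% (n=%d)\n",
              100 * x$annotate$lpc_prop_mean, 100 * x$annotate$lpc_prop_sd,
              x$annotate$n_individuals))
  cat(sprintf("  modules: %d; nearest spatial type to LPC: %s\n",
              x$modules$k, x$spatial$nearest_type))
  cat(sprintf("  wall clock: %.1f s\n", x$wall_clock_sec))
  invisible(x)
}
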
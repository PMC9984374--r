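default_config <- function() {
  list(
    seed = 1L,
    temperature = 300,
    synth = list(n_frames = 1000L, populations = c(0.6, 0.3, 0.1)),
    input = list(ensemble_path = NULL),
    descriptor = list(cutoff = 5, n_max = 6, l_max = 4, atom_sigma = 0.4,
                      normalize = TRUE),
    pca = list(n_components = 2),
    clustering = list(n_grid = 1000L, f_points = 0.008, alpha = 0.9,
                      bandwidth = "silverman", start_index = 1L),
    hbond = list(cutoff = 4.5, participation_threshold = 0.01,
                 surface_width = 0.025),
    spectra = list(fwhm = 10, grid_from = 500, grid_to = 3700, grid_by = 1,
                   v_oi = 5, noise_sd = 0, scale_factor = 1),
    output_dir = NULL
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, fills in documented defaults, and rejects
#' unknown keys.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file (CLI-style
#'   overrides).
#' @return a validated config list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  merge_block <- function(base, upd, where) {
    unknown <- setdiff(names(upd), names(base))
    if (length(unknown) > 0) {
      abort(paste0("unknown config key(s) in ", where, ": ",
                   paste(unknown, collapse = ", ")))
    }
    for (k in names(upd)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]])) {
        merge_block(base[[k]], upd[[k]], paste0(where, "$", k))
      } else upd[[k]]
    }
    base
  }
  cfg <- merge_block(cfg, user, "config")
  cfg <- merge_block(cfg, overrides, "overrides")
  cfg
}

#' Run the full clustering-to-spectrum pipeline
#'
#' Executes every stage on synthetic (default) or user-supplied data:
#' ensemble generation or loading, SOAP descriptors, PCA, PAMM clustering,
#' canonical weights and representatives, hydrogen-bond statistics,
#' broadening, weighted ensemble averaging, the hierarchical merge series,
#' and the Pendry region report against the reference spectrum.
#' Deterministic for a fixed seed.
#'
#' @param config a config list from [load_config()] (or a partial list of
#'   overrides applied to the defaults).
#' @param basins optional list of [basin_spec]s overriding the default
#'   three-basin study conditions.
#' @param spectra_provider optional `function(frame) -> stick tibble`; by
#'   default the synthetic ground-truth per-frame stick spectra are used.
#' @param reference optional reference grid spectrum tibble; by default the
#'   synthetic noise-free (or noisy, per config) reference is generated.
#' @return an object of class `run_report`: list with `config`, `ensemble`,
#'   `truth`, `descriptors`, `pca`, `model`, `clusters`, `summary_table`,
#'   `merge_tree`, `cluster_spectra`, `ensemble_spectrum`, `series`,
#'   `reference`, `pendry_report`.
#' @export
run_pipeline <- function(config = list(), basins = NULL,
                         spectra_provider = NULL, reference = NULL) {
  cfg <- if (identical(names(config), names(default_config()))) config else {
    load_config(NULL, overrides = config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  truth <- NULL
  if (!is.null(cfg$input$ensemble_path)) {
    ens <- stage("load", read_ensemble(cfg$input$ensemble_path))
    if (is.null(spectra_provider)) {
      abort("a `spectra_provider` is required when loading an external ensemble")
    }
  } else {
    if (is.null(basins)) basins <- default_basins(cfg$synth$populations)
    gen <- stage("generate", generate_ensemble(basins, cfg$synth$n_frames,
                                               cfg$temperature, cfg$seed))
    ens <- gen$ensemble
    truth <- gen$truth
    if (is.null(spectra_provider)) {
      spectra_provider <- function(frame) frame_stick_spectrum(truth, frame)
    }
  }
  sp <- stage("descriptors", compute_soap(ens, soap_params(
    cutoff = cfg$descriptor$cutoff, n_max = cfg$descriptor$n_max,
    l_max = cfg$descriptor$l_max, atom_sigma = cfg$descriptor$atom_sigma,
    species = unique(ens$species), normalize = cfg$descriptor$normalize)))
  proj <- stage("pca", pca_project(sp, cfg$pca$n_components))
  n_grid <- min(cfg$clustering$n_grid, nrow(proj$projected))
  fit <- stage("clustering", pamm(proj$projected, ens, n_grid = n_grid,
                                  start_index = cfg$clustering$start_index,
                                  f_points = cfg$clustering$f_points,
                                  alpha = cfg$clustering$alpha,
                                  bandwidth = cfg$clustering$bandwidth))
  clusters <- fit$clusters
  counts <- stage("hbond", count_hbonds(
    ens, frames = seq_along(ens$coords), cutoff = cfg$hbond$cutoff,
    participation_threshold = cfg$hbond$participation_threshold))
  summary_table <- stage("hbond_summary", per_cluster_summary(
    counts, clusters, cfg$temperature, cfg$hbond$surface_width))
  grid <- seq(cfg$spectra$grid_from, cfg$spectra$grid_to, by = cfg$spectra$grid_by)
  cluster_spectra <- stage("broaden", {
    out <- lapply(seq_len(clusters$n_clusters), function(cl) {
      sticks <- spectra_provider(clusters$representative[cl])
      if (is.null(sticks)) abort(sprintf("no stick spectrum for cluster %d", cl))
      broaden(sticks, fwhm = cfg$spectra$fwhm, grid = grid,
              scale_factor = cfg$spectra$scale_factor)
    })
    names(out) <- as.character(seq_len(clusters$n_clusters))
    out
  })
  ens_spec <- stage("ensemble_average",
                    ensemble_average(cluster_spectra, clusters$weights))
  tree <- NULL; series <- NULL
  if (clusters$n_clusters >= 2) {
    tree <- stage("merge", merge_hierarchy(clusters, fit$model, ens))
    series <- stage("series", hierarchical_series(tree, cluster_spectra))
  } else {
    series <- list(`1` = ens_spec)
  }
  if (is.null(reference)) {
    if (is.null(truth)) abort("a `reference` spectrum is required for external data")
    reference <- stage("reference", generate_reference_spectrum(
      truth, fwhm = cfg$spectra$fwhm, noise_sd = cfg$spectra$noise_sd,
      seed = cfg$seed, grid = grid))
    truth$reference_spectrum <- reference
  }
  pendry <- stage("pendry", region_report(ens_spec, reference,
                                          v_oi = cfg$spectra$v_oi))
  report <- structure(
    list(config = cfg, ensemble = ens, truth = truth, descriptors = sp,
         pca = proj, model = fit$model, clusters = clusters,
         hbond_counts = counts, summary_table = summary_table,
         merge_tree = tree, cluster_spectra = cluster_spectra,
         ensemble_spectrum = ens_spec, series = series,
         reference = reference, pendry_report = pendry,
         spectra_provider = spectra_provider),
    class = "run_report")
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d frames -> %d clusters\n",
              length(x$ensemble$coords), x$clusters$n_clusters))
  print(x$summary_table)
  print(x$pendry_report)
  invisible(x)
}

#' Re-run only the spectral stages of a finished report
#'
#' Reuses the cached ensemble, descriptors and clustering unchanged and
#' recomputes broadening, averaging, the hierarchical series and the Pendry
#' report with new spectra parameters.
#'
#' @param report a `run_report`.
#' @param spectra named list of spectra-stage parameters to change
#'   (`fwhm`, `v_oi`, `grid_from`, `grid_to`, `grid_by`, `noise_sd`,
#'   `scale_factor`).
#' @return an updated `run_report`.
#' @export
rerun_spectra <- function(report, spectra = list()) {
  cfg <- report$config
  for (k in names(spectra)) {
    if (!k %in% names(cfg$spectra)) abort(paste0("unknown spectra key: ", k))
    cfg$spectra[[k]] <- spectra[[k]]
  }
  grid <- seq(cfg$spectra$grid_from, cfg$spectra$grid_to, by = cfg$spectra$grid_by)
  clusters <- report$clusters
  cluster_spectra <- lapply(seq_len(clusters$n_clusters), function(cl) {
    broaden(report$spectra_provider(clusters$representative[cl]),
            fwhm = cfg$spectra$fwhm, grid = grid,
            scale_factor = cfg$spectra$scale_factor)
  })
  names(cluster_spectra) <- as.character(seq_len(clusters$n_clusters))
  ens_spec <- ensemble_average(cluster_spectra, clusters$weights)
  series <- if (!is.null(report$merge_tree)) {
    hierarchical_series(report$merge_tree, cluster_spectra)
  } else list(`1` = ens_spec)
  reference <- if (!is.null(report$truth)) {
    generate_reference_spectrum(report$truth, fwhm = cfg$spectra$fwhm,
                                noise_sd = cfg$spectra$noise_sd,
                                seed = cfg$seed, grid = grid)
  } else report$reference
  report$config <- cfg
  report$cluster_spectra <- cluster_spectra
  report$ensemble_spectrum <- ens_spec
  report$series <- series
  report$reference <- reference
  report$pendry_report <- region_report(ens_spec, reference, v_oi = cfg$spectra$v_oi)
  report
}

#' Within-cluster spectral consistency matrix
#'
#' Selects `n_fps` members of a cluster by farthest point sampling in the
#' projected space, broadens each member's stick spectrum, and computes the
#' Pendry factor between every selected member and every cluster
#' representative. A summary compares the mean within-cluster factor to the
#' mean against all other clusters.
#'
#' @param report a `run_report`.
#' @param cluster_id cluster whose members are probed.
#' @param n_fps number of FPS-selected members (capped at cluster size with
#'   a warning).
#' @param region evaluation window (cm^-1).
#' @return list with `matrix` (n_fps x n_clusters of R_P values, rows named
#'   by frame index), `within_mean`, `cross_mean`.
#' @export
within_cluster_consistency <- function(report, cluster_id, n_fps = 5,
                                       region = c(600, 1800)) {
  clusters <- report$clusters
  members <- which(clusters$labels == cluster_id)
  if (n_fps > length(members)) {
    warn(sprintf("n_fps = %d exceeds cluster size %d: capped", n_fps, length(members)))
    n_fps <- length(members)
  }
  Xm <- report$pca$projected[members, , drop = FALSE]
  sel <- members[farthest_point_sampling(Xm, n_fps)]
  cfg <- report$config
  grid <- seq(cfg$spectra$grid_from, cfg$spectra$grid_to, by = cfg$spectra$grid_by)
  spec_of <- function(frame) {
    broaden(report$spectra_provider(frame), fwhm = cfg$spectra$fwhm, grid = grid,
            scale_factor = cfg$spectra$scale_factor)
  }
  member_specs <- lapply(sel, spec_of)
  rep_specs <- lapply(clusters$representative, spec_of)
  M <- matrix(NA_real_, n_fps, clusters$n_clusters,
              dimnames = list(as.character(sel),
                              as.character(seq_len(clusters$n_clusters))))
  for (i in seq_len(n_fps)) {
    for (j in seq_len(clusters$n_clusters)) {
      M[i, j] <- pendry_r(member_specs[[i]], rep_specs[[j]],
                          v_oi = cfg$spectra$v_oi, region = region)$r_p
    }
  }
  list(matrix = M,
       within_mean = mean(M[, cluster_id]),
       cross_mean = if (clusters$n_clusters > 1)
         mean(M[, -cluster_id, drop = FALSE]) else NA_real_)
}

#' Write the tabular artifacts of a run report to disk
#'
#' Emits the cluster summary table, per-frame labels, merge tree (JSON and
#' Newick), per-cluster and ensemble spectra, and the Pendry region report
#' as plain-text files.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary_table, file.path(dir, "cluster_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(tibble::tibble(frame = seq_along(report$clusters$labels),
                                  cluster = report$clusters$labels),
                   file.path(dir, "frame_labels.csv"), row.names = FALSE)
  utils::write.csv(report$pendry_report, file.path(dir, "pendry_report.csv"),
                   row.names = FALSE)
  write_spectrum(report$ensemble_spectrum, file.path(dir, "ensemble_spectrum.dat"))
  for (nm in names(report$cluster_spectra)) {
    write_spectrum(report$cluster_spectra[[nm]],
                   file.path(dir, paste0("cluster_", nm, "_spectrum.dat")))
  }
  if (!is.null(report$merge_tree)) {
    write_newick(report$merge_tree, file.path(dir, "merge_tree.nwk"))
    jsonlite::write_json(report$merge_tree$merges, file.path(dir, "merge_tree.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(seed = report$config$seed,
         weights = report$clusters$weights,
         representatives = report$clusters$representative),
    file.path(dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
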
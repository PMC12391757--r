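#' Configuration for an end-to-end run
#'
#' @param mode `"synthetic"` generates all inputs from
#'   [synthetic_config()]; `"directory"` loads a cohort directory written
#'   by [write_cohort()].
#' @param synthetic a [synthetic_config()] (synthetic mode).
#' @param data_dir cohort directory (directory mode).
#' @param out_dir output directory for all products.
#' @param r_min functional disconnection threshold (r-value, default 0.2).
#' @param p_min structural disconnection threshold (probability,
#'   exclusive, default 0.5).
#' @param exclusion_pct parcel exclusion threshold in percent (default 5).
#' @param feature_value overlap measure filling design-matrix cells:
#'   `"lesion_pct"` (spatial distribution of the lesion, the default),
#'   `"parcel_pct"` (fraction of each parcel damaged — the
#'   parameterization the synthetic outcome model is linear in) or
#'   `"both"`.
#' @param lambda_n,lambda_low,lambda_high Lasso grid settings (100 values,
#'   1e-5 to 1e5).
#' @param n_perm permutations for voxel-wise inference (default 1000).
#' @param alpha FWE significance level (default 0.01).
#' @param min_coverage voxel inclusion: minimal subjects with nonzero
#'   values.
#' @param tfce TFCE settings, a [tfce_params()].
#' @param seed master seed; every stage derives its own sub-seed from it
#'   by a fixed offset so stages are independently reproducible.
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "directory"),
                       synthetic = synthetic_config(),
                       data_dir = NULL,
                       out_dir = tempfile("netlesion_run_"),
                       r_min = 0.2, p_min = 0.5, exclusion_pct = 5,
                       feature_value = c("lesion_pct", "parcel_pct",
                                         "both"),
                       lambda_n = 100L, lambda_low = 1e-5,
                       lambda_high = 1e5,
                       n_perm = 1000L, alpha = 0.01, min_coverage = 5L,
                       tfce = tfce_params(), seed = 42L) {
  mode <- match.arg(mode)
  feature_value <- match.arg(feature_value)
  if (mode == "directory" && is.null(data_dir))
    stop("directory mode requires data_dir")
  if (r_min < -1 || r_min > 1) stop("r_min must lie in [-1, 1]")
  if (p_min < 0 || p_min > 1) stop("p_min must lie in [0, 1]")
  if (exclusion_pct < 0) stop("exclusion_pct must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(mode = mode, synthetic = synthetic, data_dir = data_dir,
                 out_dir = out_dir, r_min = r_min, p_min = p_min,
                 exclusion_pct = exclusion_pct,
                 feature_value = feature_value, lambda_n = lambda_n,
                 lambda_low = lambda_low, lambda_high = lambda_high,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 min_coverage = as.integer(min_coverage), tfce = tfce,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_prediction_json <- function(res, path) {
  jsonlite::write_json(
    list(model_id = res$model_id, lambda_selected = res$lambda_selected,
         r2 = res$r2, r2_insample = res$r2_insample, loo_sd = res$loo_sd,
         delta_vs_benchmark = res$delta_vs_benchmark,
         coefficients = as.list(res$coefficients),
         loo_predictions = as.list(res$loo_predictions)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Run the full lesion-topography analysis
#'
#' Executes, in order: input generation or loading; per-atlas overlap
#' features with the dual-percentage exclusion rule; functional and
#' structural disconnection maps with their thresholds; Lasso/LOO outcome
#' models (three atlases, clinical benchmark, atlas+covariate combinations)
#' with the model-comparison table; voxel-wise TFCE permutation inference
#' on lesion topography, functional and structural disconnection (positive
#' and negative contrasts); the per-network disconnection-outcome
#' correlation; and the tract overlap report on the significant structural
#' mask. All products are written under `config$out_dir` and indexed in
#' the returned manifest (also saved as `manifest.json`). A rerun with the
#' same config and seed reproduces all tabular products identically.
#'
#' @param config a [run_config()].
#' @return The manifest: a list with `paths`, `summary`, `config_echo` and
#'   `versions`.
#' @export
run_all <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  t0 <- Sys.time()
  log_stage <- function(stage, t_start)
    message(sprintf("[netlesion] %-12s %6.1fs", stage,
                    as.numeric(Sys.time() - t_start, units = "secs")))

  ## --- inputs -----------------------------------------------------------
  ts <- Sys.time()
  if (config$mode == "synthetic") {
    syn <- config$synthetic
    syn$seed <- config$seed + 1000L
    atl <- tryCatch(make_atlases(syn),
                    error = function(e) stop("stage simulate: ",
                                             conditionMessage(e)))
    connectome <- make_connectome(syn, atl$network)
    cohort <- make_cohort(syn, atl, atl$tracts)
    cohort_dir <- file.path(out, "cohort")
    write_cohort(cohort, atl, connectome, cohort_dir)
    lesions <- cohort$lesions
    outcomes <- cohort$outcomes
    atlases <- atl[c("vascular", "network", "wm")]
    bm <- atl$brainmask
    tracts <- atl$tracts
    paths$cohort_dir <- cohort_dir
  } else {
    loaded <- tryCatch(load_cohort(config$data_dir),
                       error = function(e) stop("stage load: ",
                                                conditionMessage(e)))
    lesions <- loaded$lesions
    outcomes <- loaded$outcomes
    atlases <- loaded$atlases
    bm <- loaded$brainmask
    connectome <- loaded$connectome
    tracts <- loaded$tracts
    paths$cohort_dir <- config$data_dir
  }
  y <- as.numeric(outcomes$mrs)
  log_stage("inputs", ts)

  ## --- atlas overlap features ------------------------------------------
  ts <- Sys.time()
  grid <- lambda_grid(config$lambda_n, config$lambda_low,
                      config$lambda_high)
  design <- list()
  paths$feature_tables <- character(0)
  for (nm in names(atlases)) {
    feats <- lapply(lesions, function(les) {
      f <- compute_overlap(les, atlases[[nm]],
                           threshold_pct = config$exclusion_pct)
      apply_exclusion(f, config$exclusion_pct)
    })
    design[[nm]] <- build_design_matrix(feats, atlases[[nm]],
                                        value = config$feature_value)
    p <- file.path(out, sprintf("features_%s.tsv", nm))
    write_design_matrix(design[[nm]], p)
    paths$feature_tables[nm] <- p
  }
  log_stage("features", ts)

  ## --- disconnection maps ----------------------------------------------
  ts <- Sys.time()
  fdir <- file.path(out, "fdisc"); dir.create(fdir, showWarnings = FALSE)
  sdir <- file.path(out, "sdisc"); dir.create(sdir, showWarnings = FALSE)
  fmaps <- tryCatch(functional_disconnection_maps(lesions, connectome),
                    error = function(e) stop("stage disconnect: ",
                                             conditionMessage(e)))
  fthr <- lapply(fmaps, threshold_map, r_min = config$r_min)
  smaps <- if (!is.null(tracts))
    structural_disconnection_maps(lesions, tracts) else NULL
  sthr <- if (!is.null(smaps))
    lapply(smaps, threshold_structural, p_min = config$p_min) else NULL
  for (i in seq_along(lesions)) {
    id <- lesions[[i]]$subject_id
    write_volume(fmaps[[i]]$values, bm$grid,
                 file.path(fdir, sprintf("%s_fdisc.nii.gz", id)))
    if (!is.null(smaps))
      write_volume(smaps[[i]]$values, bm$grid,
                   file.path(sdir, sprintf("%s_sdisc.nii.gz", id)))
  }
  paths$fdisc_dir <- fdir
  if (!is.null(smaps)) paths$sdisc_dir <- sdir
  log_stage("disconnect", ts)

  ## --- outcome prediction ----------------------------------------------
  ts <- Sys.time()
  mdir <- file.path(out, "models"); dir.create(mdir, showWarnings = FALSE)
  models <- list()
  for (nm in names(design)) {
    models[[nm]] <- fit_lasso_loo(design[[nm]], y, grid, model_id = nm)
    models[[paste0(nm, "_combined")]] <-
      combined_model(design[[nm]], outcomes, grid,
                     atlas_result = models[[nm]],
                     model_id = paste0(nm, "_combined"))
  }
  models$benchmark <- benchmark_model(outcomes, grid)
  paths$model_files <- character(0)
  for (nm in names(models)) {
    p <- file.path(mdir, paste0(nm, ".json"))
    write_prediction_json(models[[nm]], p)
    paths$model_files[nm] <- p
  }
  comparison <- compare_models(models)
  paths$model_comparison <- file.path(out, "model_comparison.tsv")
  write.table(comparison, paths$model_comparison, sep = "\t",
              row.names = FALSE, quote = FALSE)
  log_stage("predict", ts)

  ## --- voxel-wise inference --------------------------------------------
  ts <- Sys.time()
  vdir <- file.path(out, "stats"); dir.create(vdir, showWarnings = FALSE)
  feature_maps <- list(lesion = lesions, functional = fthr)
  if (!is.null(sthr)) feature_maps$structural <- sthr
  inference <- list()
  paths$inference <- character(0)
  feat_i <- 0L
  for (feat in names(feature_maps)) {
    feat_i <- feat_i + 1L
    for (dir_i in 1:2) {
      direction <- c("positive", "negative")[dir_i]
      key <- paste0(feat, "_", substr(direction, 1, 3))
      res <- tryCatch(
        permutation_fwe(feature_maps[[feat]], y, bm, params = config$tfce,
                        n_perm = config$n_perm, alpha = config$alpha,
                        direction = direction,
                        min_coverage = config$min_coverage,
                        seed = config$seed + 2000L + 10L * feat_i + dir_i),
        error = function(e) stop("stage voxelwise: ",
                                 conditionMessage(e)))
      inference[[key]] <- res
      for (prod in c("tstat", "tfce", "fwep", "sig")) {
        arr <- switch(prod, tstat = res$t_values,
                      tfce = res$tfce_observed, fwep = res$fwe_p,
                      sig = res$significant + 0)
        write_volume(arr, bm$grid,
                     file.path(vdir, sprintf("%s_%s_%s.nii.gz", feat,
                                             prod, substr(direction, 1, 3))))
      }
      paths$inference[key] <- file.path(vdir, sprintf("%s_*_%s.nii.gz",
                                                      feat,
                                                      substr(direction, 1, 3)))
    }
  }
  log_stage("voxelwise", ts)

  ## --- network correlation and tract report ----------------------------
  ts <- Sys.time()
  netcor <- network_outcome_correlation(fthr, atlases$network, y)
  paths$network_correlation <- file.path(out, "network_correlation.tsv")
  write.table(netcor, paths$network_correlation, sep = "\t",
              row.names = FALSE, quote = FALSE)
  tract_report <- NULL
  if (!is.null(tracts) && !is.null(inference$structural_pos)) {
    tract_report <- tract_overlap_report(
      inference$structural_pos$significant, tracts)
    paths$tract_report <- file.path(out, "tract_overlap.tsv")
    write.table(tract_report, paths$tract_report, sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  log_stage("reports", ts)

  summary <- list(
    n_subjects = length(lesions),
    model_r2 = setNames(lapply(models, `[[`, "r2"), names(models)),
    n_significant = lapply(inference, function(r) sum(r$significant)),
    top_network = netcor$network[which.max(netcor$r2)],
    elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
  cfg_echo <- config
  cfg_echo$tfce <- unclass(cfg_echo$tfce)
  cfg_echo$synthetic <- unclass(cfg_echo$synthetic)
  manifest <- list(paths = paths, summary = summary,
                   config_echo = unclass(cfg_echo),
                   versions = list(
                     netlesion = as.character(utils::packageVersion("netlesion")),
                     R = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  manifest$models <- models
  manifest$inference <- inference
  manifest$network_correlation <- netcor
  manifest$tract_report <- tract_report
  manifest$comparison <- comparison
  invisible(manifest)
}
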
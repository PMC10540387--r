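#' Save a calibrated PLS model as versioned JSON
#'
#' Serializes the full frozen prediction transform: centering statistics,
#' NIPALS weights/loadings, regression vector, pretreatment (including any
#' MSC reference), windows, grid, trait and calibration ids.
#'
#' @param m A [calibrate_model()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(m, path) {
  stopifnot(inherits(m, "pls_model"))
  obj <- list(
    schema = "stalknirs-pls-model/1",
    trait_name = m$trait_name, units = m$units, rank = m$rank,
    grid = m$grid,
    windows = if (is.null(m$windows)) NULL else m$windows$intervals,
    pretreatment = list(method = m$pretreatment$method,
                        sg_window = m$pretreatment$sg_window,
                        sg_polyorder = m$pretreatment$sg_polyorder,
                        msc_reference = m$pretreatment$msc_reference),
    fit = list(x_mean = m$fit$x_mean, y_mean = m$fit$y_mean,
               weights = m$fit$weights, x_loadings = m$fit$x_loadings,
               y_loadings = m$fit$y_loadings,
               coefficients = m$fit$coefficients, rank = m$fit$rank),
    y_mean = m$y_mean, sd_ref = m$sd_ref,
    calibration_ids = m$calibration_ids)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "columnmajor")
  invisible(path)
}

#' Load a calibrated PLS model from JSON
#'
#' @param path Path written by [save_model()].
#' @return A `pls_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "stalknirs-pls-model/1")) {
    stop("unrecognized model schema: ", obj$schema)
  }
  pt <- pretreatment(obj$pretreatment$method,
                     sg_window = obj$pretreatment$sg_window,
                     sg_polyorder = obj$pretreatment$sg_polyorder)
  pt$msc_reference <- obj$pretreatment$msc_reference
  p <- length(obj$fit$x_mean)
  fit <- structure(list(
    rank = as.integer(obj$fit$rank),
    x_mean = as.numeric(obj$fit$x_mean), y_mean = obj$fit$y_mean,
    weights = matrix(unlist(obj$fit$weights), nrow = p),
    x_loadings = matrix(unlist(obj$fit$x_loadings), nrow = p),
    y_loadings = as.numeric(obj$fit$y_loadings),
    coefficients = as.numeric(obj$fit$coefficients)), class = "pls_fit")
  windows <- if (is.null(obj$windows) || length(obj$windows) == 0L) NULL else {
    window_set(lapply(seq_len(nrow(as.matrix(obj$windows))), function(i)
      as.numeric(as.matrix(obj$windows)[i, ])))
  }
  structure(list(fit = fit, pretreatment = pt, windows = windows,
                 grid = as.numeric(obj$grid), full_grid = NULL,
                 trait_name = obj$trait_name, units = obj$units,
                 calibration_ids = as.character(obj$calibration_ids),
                 y_mean = obj$y_mean, sd_ref = obj$sd_ref,
                 rank = as.integer(obj$rank)),
            class = "pls_model")
}

#' Configure an end-to-end calibration run
#'
#' Validated before any stage runs; serialized into every output for
#' provenance.
#'
#' @param spectra Path to a wide spectra CSV, or a [spectra_set()].
#' @param reference Path to a reference CSV, or a [reference_table()].
#' @param mode Spectra mode when reading from file.
#' @param candidate_pretreatments Method names for the search.
#' @param candidate_windows List of [window_set()]s (`NULL` = full range).
#' @param max_rank,n_segments,split_ratio,seed Search settings.
#' @param gh_threshold GH flagging cutoff; `remove_outliers` drops flagged
#'   samples before the split when `TRUE` (they are always reported).
#' @param pca_k PCA depth for the QC stage.
#' @param global Also run the merged-set global recalibration.
#' @param out_dir Output directory for artifacts.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(spectra, reference, mode = "absorbance",
                            candidate_pretreatments = c("NONE", "SNV", "MSC",
                                                        "FD_SNV"),
                            candidate_windows = list(NULL),
                            max_rank = 15L, n_segments = 10L,
                            split_ratio = 0.8, seed = 1L,
                            gh_threshold = 3, remove_outliers = FALSE,
                            pca_k = 10L, global = TRUE, out_dir = tempdir()) {
  if (!all(candidate_pretreatments %in% PRETREATMENT_METHODS)) {
    bad <- setdiff(candidate_pretreatments, PRETREATMENT_METHODS)
    stop("unknown pretreatment method(s): ", paste(bad, collapse = ", "))
  }
  if (!(split_ratio > 0 && split_ratio < 1)) stop("split_ratio must be in (0, 1)")
  if (max_rank < 1L) stop("max_rank must be at least 1")
  if (n_segments < 2L) stop("n_segments must be at least 2")
  if (gh_threshold <= 0) stop("gh_threshold must be positive")
  structure(list(spectra = spectra, reference = reference, mode = mode,
                 candidate_pretreatments = candidate_pretreatments,
                 candidate_windows = candidate_windows,
                 max_rank = as.integer(max_rank),
                 n_segments = as.integer(n_segments),
                 split_ratio = split_ratio, seed = as.integer(seed),
                 gh_threshold = gh_threshold,
                 remove_outliers = isTRUE(remove_outliers),
                 pca_k = as.integer(pca_k), global = isTRUE(global),
                 out_dir = out_dir),
            class = "pipeline_config")
}

config_fingerprint <- function(cfg) {
  echo <- cfg
  echo$out_dir <- NULL   # fingerprint the analysis settings, not the destination
  echo$spectra <- if (is.character(cfg$spectra)) cfg$spectra else "<in-memory>"
  echo$reference <- if (is.character(cfg$reference)) cfg$reference else "<in-memory>"
  echo$candidate_windows <- vapply(cfg$candidate_windows, format_windows,
                                   character(1))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(echo), tmp, auto_unbox = TRUE, digits = NA)
  list(echo = echo, hash = unname(tools::md5sum(tmp)))
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full calibration workflow
#'
#' Reads data, screens spectra with the GH distance, splits into calibration
#' and validation sets, searches pretreatment x window combinations by
#' cross-validation, fits the best model, validates it externally, and
#' (optionally) recalibrates on the merged set. Artifacts written to
#' `cfg$out_dir`: `model.json`, `leaderboard.csv`, `report.csv` (the
#' calibration/CV/external statistic set), `gh_report.csv`,
#' `predicted_vs_observed.csv`, `run_log.txt`.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the split, search, best model, external
#'   validation, optional global report, GH report, and the report row.
#' @export
run_calibrate <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  fp <- config_fingerprint(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("stalknirs %s calibrate",
                         as.character(utils::packageVersion("stalknirs"))),
                 sprintf("seed: %d", cfg$seed),
                 sprintf("config_hash: %s", fp$hash))

  s <- pipeline_stage("read_spectra",
    if (inherits(cfg$spectra, "spectra_set")) cfg$spectra
    else read_spectra(cfg$spectra, mode = cfg$mode))
  ref <- pipeline_stage("read_reference",
    if (inherits(cfg$reference, "reference_table")) cfg$reference
    else read_reference(cfg$reference))

  pca <- pipeline_stage("qc_pca",
    fit_pca(s, k = min(cfg$pca_k, nrow(s$values) - 1L, ncol(s$values))))
  gh <- pipeline_stage("qc_gh", gh_distance(pca, s, threshold = cfg$gh_threshold))
  log_lines <- c(log_lines, sprintf("QC: %d of %d spectra flagged at GH > %g",
                                    sum(gh$flag), nrow(gh), cfg$gh_threshold))
  if (cfg$remove_outliers && any(gh$flag)) {
    keep <- !s$sample_ids %in% gh$sample_id[gh$flag]
    s <- s[keep]
    ref <- ref[ref$sample_id %in% s$sample_ids, , drop = FALSE]
  }

  split <- pipeline_stage("split",
    split_calibration_validation(ref, ratio = cfg$split_ratio,
                                 seed = cfg$seed))
  s_cal <- s[split$calibration]
  ref_cal <- ref[match(split$calibration, ref$sample_id), , drop = FALSE]
  s_val <- s[split$validation]
  ref_val <- ref[match(split$validation, ref$sample_id), , drop = FALSE]

  search <- pipeline_stage("grid_search",
    grid_search(s_cal, ref_cal,
                candidate_pretreatments = cfg$candidate_pretreatments,
                candidate_windows = cfg$candidate_windows,
                max_rank = cfg$max_rank, n_segments = cfg$n_segments,
                seed = cfg$seed))
  best <- search$models[[1L]]
  ext <- pipeline_stage("external_validation",
    external_validate(best, s_val, ref_val))

  report <- search$leaderboard[1L, , drop = FALSE]
  report$N_val <- ext$n
  report$RMSEP <- ext$RMSEP
  report$R2ev <- ext$R2ev
  report$RPD_ev <- ext$RPD

  glob <- NULL
  if (cfg$global) {
    glob <- pipeline_stage("global_recalibration",
      global_recalibrate(split, s, ref, pretreat = best$pretreatment$method,
                         windows = best$windows, max_rank = cfg$max_rank,
                         n_segments = cfg$n_segments, seed = cfg$seed))
  }

  # artifacts
  save_model(best, file.path(cfg$out_dir, "model.json"))
  lb <- search$leaderboard
  lb$seed <- cfg$seed
  lb$config_hash <- fp$hash
  utils::write.csv(lb, file.path(cfg$out_dir, "leaderboard.csv"),
                   row.names = FALSE)
  rep_out <- report
  rep_out$stage_global_RMSECV <- if (is.null(glob)) NA else glob$report$RMSECV
  rep_out$stage_global_R2cv <- if (is.null(glob)) NA else glob$report$R2cv
  rep_out$seed <- cfg$seed
  rep_out$config_hash <- fp$hash
  utils::write.csv(rep_out, file.path(cfg$out_dir, "report.csv"),
                   row.names = FALSE)
  ghr <- as.data.frame(gh)
  ghr$seed <- cfg$seed
  utils::write.csv(ghr, file.path(cfg$out_dir, "gh_report.csv"),
                   row.names = FALSE)
  pvo <- data.frame(
    sample_id = c(split$calibration, split$validation),
    set = rep(c("calibration", "validation"),
              c(length(split$calibration), length(split$validation))),
    observed = c(ref_cal$value, ref_val$value),
    predicted = c(best$fit$fitted, unname(ext$predictions)))
  utils::write.csv(pvo, file.path(cfg$out_dir, "predicted_vs_observed.csv"),
                   row.names = FALSE)
  log_lines <- c(log_lines,
                 sprintf("best: %s %s rank %d", report$pretreatment,
                         report$windows, report$rank),
                 sprintf("RMSEC %.4g R2 %.4f RPD %.4g", report$RMSEC,
                         report$R2, report$RPD_cal),
                 sprintf("RMSECV %.4g R2cv %.4f RPD %.4g", report$RMSECV,
                         report$R2cv, report$RPD_cv),
                 sprintf("RMSEP %.4g R2ev %.4f RPD %.4g", report$RMSEP,
                         report$R2ev, report$RPD_ev))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))

  invisible(list(split = split, search = search, model = best,
                 external = ext, global = glob, gh = gh, report = report,
                 config_hash = fp$hash))
}

#' Predict new spectra with a saved model
#'
#' @param model_path Path to a [save_model()] JSON artifact.
#' @param spectra_path Path to a wide spectra CSV.
#' @param out_path Optional output CSV; when given, predictions are written
#'   with the model trait and units.
#' @param mode Spectra mode of the input file.
#' @return A data.frame with columns `sample_id`, `predicted`, `trait`,
#'   `units`.
#' @export
run_predict <- function(model_path, spectra_path, out_path = NULL,
                        mode = "absorbance") {
  m <- load_model(model_path)
  s <- read_spectra(spectra_path, mode = mode)
  pred <- predict(m, s)
  out <- data.frame(sample_id = names(pred), predicted = unname(pred),
                    trait = m$trait_name, units = m$units,
                    stringsAsFactors = FALSE)
  if (!is.null(out_path)) {
    utils::write.csv(out, out_path, row.names = FALSE)
  }
  out
}
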
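# End-to-end pipeline wrappers behind the command-line interface
# (inst/cli/roinet). Results go to CSV files; a JSON manifest records the
# configuration and seeds of every run.

write_manifest <- function(out_dir, stage, config, seeds, inputs = character(0),
                           timing = NULL) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("roinet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    seeds = seeds,
    input_md5 = if (length(inputs)) as.list(tools::md5sum(inputs)) else list(),
    timing_sec = timing
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

models_to_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(target = m$target,
               target_label = m$target_label %||% NA_character_,
               predictor = m$predictors,
               predictor_label = m$labels %||% NA_character_,
               weight = m$weights, std_weight = m$std_weights,
               offset = m$offset, fit_method = m$fit_method,
               validation_error = m$validation_error)
  }))
}

table_to_models <- function(tab) {
  lapply(split(tab, tab$target), function(d) {
    new_roi_model(d$target[1L], d$predictor, d$weight,
                  fit_method = d$fit_method[1L], std_weights = d$std_weight,
                  offset = d$offset[1L],
                  validation_error = d$validation_error[1L],
                  labels = d$predictor_label,
                  target_label = d$target_label[1L])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write synthetic subject files to a directory
#'
#' Simulates one subject from a ground-truth scenario and writes
#' `activity.csv`, `parcels.csv`, `meta.csv`, a `truth.json` dump of the
#' dependency structure, and a run manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param gt A [make_scenario()] ground truth (default scenario if omitted).
#' @param n_timepoints Series length.
#' @param seed Noise seed.
#' @return Invisibly, `out_dir`.
#' @export
simulate_subject_files <- function(out_dir, gt = make_scenario(),
                                   n_timepoints = 660L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(gt, n_timepoints, seed = seed)
  write_roi_dataset(ds, file.path(out_dir, "activity.csv"),
                    file.path(out_dir, "parcels.csv"),
                    file.path(out_dir, "meta.csv"))
  truth <- list(n_rois = gt$n_rois, integrators = gt$integrators,
                drivers = gt$drivers, low_tsnr = gt$low_tsnr,
                coupled_pairs = gt$coupled_pairs,
                weight_matrix = gt$weight_matrix, structure_seed = gt$seed,
                noise_seed = seed)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "simulate",
                 config = list(n_rois = gt$n_rois,
                               k_predictors = gt$k_predictors,
                               true_weight = gt$true_weight,
                               n_timepoints = n_timepoints),
                 seeds = list(structure = gt$seed, noise = seed))
  invisible(out_dir)
}

#' Fit models for every ROI of one subject
#'
#' Loads a subject's delimited-text files, fits every ROI as target with the
#' chosen method, and writes `models.csv` (one row per predictor),
#' `metrics.csv` (one row per ROI: label, method, number of predictors,
#' test error, tSNR), RFE trace dumps when applicable, and a manifest.
#'
#' @param activity_path,parcel_path,meta_path Subject input files
#'   (see [read_roi_dataset()]).
#' @param method One of `"rfe"`, `"rfe2"`, `"lasso"`, `"enet"`, `"simple"`,
#'   `"single"`.
#' @param out_dir Output directory.
#' @param units Activity units of the input file (`"percent"` or `"raw"`).
#' @param config A [fit_config()].
#' @param seed Seed recorded in the manifest (fits are deterministic).
#' @param targets Optional subset of target ROI ids (defaults to all).
#' @return Invisibly, the metrics data frame.
#' @export
run_fit <- function(activity_path, parcel_path, meta_path = NULL,
                    method = "rfe", out_dir = ".", units = "percent",
                    config = fit_config(), seed = 1L, targets = NULL) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_roi_dataset(activity_path, parcel_path, meta_path, units = units)
  split <- split_segments(n_timepoints(ds))
  if (is.null(targets)) targets <- seq_len(n_rois(ds)) - 1L
  test_rows <- segment_rows(split, "test")
  models <- list()
  metrics <- list()
  traces <- list()
  for (tg in targets) {
    m <- fit_roi_model(ds, tg, method, split, config,
                       keep_trace = method %in% c("rfe", "rfe2"))
    obs <- roi_column(ds, tg)[test_rows]
    err <- prediction_error(obs, predict(m, ds, split, "test"))
    metrics[[length(metrics) + 1L]] <- data.frame(
      roi_id = tg, roi_label = ds$parcels$label_hemi[tg + 1L],
      method = method, n_predictors = length(m$predictors),
      test_error_pct = err,
      validation_error_pct = m$validation_error,
      tsnr = tsnr(roi_column(ds, tg)))
    if (!is.null(m$trace)) {
      tr <- m$trace
      traces[[length(traces) + 1L]] <- data.frame(
        target = tg, step = seq_along(tr$val_errors) - 1L,
        n_predictors = tr$n_predictors,
        eliminated = c(tr$eliminated, NA_integer_),
        validation_error = tr$val_errors)
      m$trace <- NULL
    }
    models[[length(models) + 1L]] <- m
  }
  metrics <- do.call(rbind, metrics)
  utils::write.csv(models_to_table(models),
                   file.path(out_dir, "models.csv"), row.names = FALSE)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  if (length(traces)) {
    utils::write.csv(do.call(rbind, traces),
                     file.path(out_dir, "rfe_trace.csv"), row.names = FALSE)
  }
  dest_meta <- file.path(out_dir, "meta.csv")
  if (!is.null(meta_path) &&
      normalizePath(meta_path) != suppressWarnings(normalizePath(dest_meta,
                                                                 mustWork = FALSE))) {
    file.copy(meta_path, dest_meta, overwrite = TRUE)
  }
  write_manifest(out_dir, "fit",
                 config = c(list(method = method, units = units),
                            unclass(config)),
                 seeds = list(seed = seed),
                 inputs = c(activity_path, parcel_path),
                 timing = proc.time()[["elapsed"]] - t0)
  invisible(metrics)
}

#' Per-ROI multiregional prediction gain for one subject
#'
#' Fits, for every target ROI, the RFE multi-predictor model and the
#' single-best-correlated-predictor baseline, and writes `gain.csv` with one
#' [multiregional_prediction_gain()] row per ROI.
#'
#' @inheritParams run_fit
#' @return Invisibly, the gain data frame.
#' @export
run_gain <- function(activity_path, parcel_path, meta_path = NULL,
                     out_dir = ".", units = "percent", config = fit_config(),
                     seed = 1L, targets = NULL) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_roi_dataset(activity_path, parcel_path, meta_path, units = units)
  split <- split_segments(n_timepoints(ds))
  if (is.null(targets)) targets <- seq_len(n_rois(ds)) - 1L
  rows <- lapply(targets, function(tg) {
    g <- multiregional_prediction_gain(ds, split, tg)
    data.frame(roi_id = tg, roi_label = ds$parcels$label_hemi[tg + 1L],
               error_multi_pct = g$error_multi,
               error_single_pct = g$error_single, gain_pct = g$gain,
               gain_p = g$p_value, single_predictor = g$single_predictor,
               n_predictors_multi = g$n_predictors_multi)
  })
  gain <- do.call(rbind, rows)
  utils::write.csv(gain, file.path(out_dir, "gain.csv"), row.names = FALSE)
  write_manifest(out_dir, "gain", config = list(units = units),
                 seeds = list(seed = seed),
                 inputs = c(activity_path, parcel_path),
                 timing = proc.time()[["elapsed"]] - t0)
  invisible(gain)
}

#' Group-level aggregation across subject result directories
#'
#' Each subject directory must contain `models.csv` and `gain.csv` (from
#' [run_fit()] and [run_gain()]) plus `parcels.csv` and `meta.csv`.
#' Integrator ROIs are those whose bootstrap-mean gain across subjects
#' exceeds `gain_threshold`; for each, key predictor ROIs are identified
#' across subjects and the resulting edges classified by centroid distance
#' and hemisphere. Partial correlations (controlling head motion) of mean
#' test error and mean gain with age are also written.
#'
#' @param subject_dirs Character vector of at least 2 subject directories.
#' @param out_dir Output directory.
#' @param gain_threshold Bootstrap-mean gain (percent) above which an ROI
#'   counts as an integrator (13).
#' @param well_modeled_error Mean multi-model test error (percent) an ROI
#'   must stay below to be classified at all (30): gain is only meaningful
#'   for regions the models actually predict, so poorly modeled ROIs are
#'   never called integrators however noisy their gain estimate.
#' @param alpha Significance level for key predictors after Bonferroni.
#' @param n_perm Null reassignments per subject for the key-predictor test.
#' @param n_boot Bootstrap resamples.
#' @param seed RNG seed.
#' @return Invisibly, a list with `key_predictors`, `edges`,
#'   `gain_summary`, `age_correlations`.
#' @export
run_group <- function(subject_dirs, out_dir = ".", gain_threshold = 13,
                      well_modeled_error = 30, alpha = 0.05, n_perm = 200L,
                      n_boot = 500L, seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  if (length(subject_dirs) < 2L) stop("need at least 2 subject directories")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  parcels <- validate_parcels(read_delim_auto(file.path(subject_dirs[1L],
                                                        "parcels.csv")))
  subs <- lapply(subject_dirs, function(d) {
    p <- validate_parcels(read_delim_auto(file.path(d, "parcels.csv")))
    if (!identical(p$label_hemi, parcels$label_hemi)) {
      stop("mismatched parcel tables across subjects (", d, ")")
    }
    list(models = table_to_models(utils::read.csv(file.path(d, "models.csv"))),
         gain = utils::read.csv(file.path(d, "gain.csv")),
         meta = utils::read.csv(file.path(d, "meta.csv"))[1L, ])
  })
  R <- nrow(parcels)

  # gain summary: bootstrap mean/CI per ROI across subjects
  gain_mat <- sapply(subs, function(s) s$gain$gain_pct[match(seq_len(R) - 1L,
                                                             s$gain$roi_id)])
  err_mat <- sapply(subs, function(s) {
    s$gain$error_multi_pct[match(seq_len(R) - 1L, s$gain$roi_id)]
  })
  gain_summary <- do.call(rbind, lapply(seq_len(R), function(i) {
    v <- gain_mat[i, ]
    if (all(is.na(v))) return(NULL)
    bs <- bootstrap_mean_ci(v[!is.na(v)], n_boot = n_boot, seed = seed + i)
    err <- mean(err_mat[i, ], na.rm = TRUE)
    data.frame(roi_id = i - 1L, roi_label = parcels$label_hemi[i],
               mean_gain_pct = bs$mean, ci_low = bs$ci[1], ci_high = bs$ci[2],
               mean_error_pct = err,
               integrator = bs$mean > gain_threshold &
                 err < well_modeled_error)
  }))
  utils::write.csv(gain_summary, file.path(out_dir, "gain_summary.csv"),
                   row.names = FALSE)

  integrators <- gain_summary$roi_id[gain_summary$integrator]
  key <- list()
  for (tg in integrators) {
    models <- lapply(subs, function(s) {
      s$models[[as.character(tg)]]
    })
    models <- Filter(Negate(is.null), models)
    if (length(models) < 2L) next
    kp <- identify_key_predictors(models, n_rois = R, n_perm = n_perm,
                                  alpha = alpha, n_boot = n_boot,
                                  seed = seed + tg)
    kp$target_label <- parcels$label_hemi[tg + 1L]
    kp$predictor_label <- parcels$label_hemi[kp$predictor + 1L]
    key[[length(key) + 1L]] <- kp
  }
  key <- if (length(key)) do.call(rbind, key) else NULL
  if (!is.null(key)) {
    utils::write.csv(key, file.path(out_dir, "key_predictors.csv"),
                     row.names = FALSE)
  }
  edges <- NULL
  if (!is.null(key) && any(key$key)) {
    edges <- classify_dependencies(key[key$key, c("target", "predictor")],
                                   parcels)
    edges$target_label <- parcels$label_hemi[edges$target + 1L]
    edges$predictor_label <- parcels$label_hemi[edges$predictor + 1L]
    utils::write.csv(edges, file.path(out_dir, "edges.csv"),
                     row.names = FALSE)
  }

  # age correlations controlling head motion
  age <- vapply(subs, function(s) as.numeric(s$meta$age_years), numeric(1))
  motion <- vapply(subs, function(s) as.numeric(s$meta$head_motion_mm),
                   numeric(1))
  age_cor <- NULL
  if (!anyNA(age) && !anyNA(motion) && length(age) >= 4L &&
      stats::sd(age) > 0) {
    mean_err <- colMeans(err_mat, na.rm = TRUE)
    mean_gain <- colMeans(gain_mat, na.rm = TRUE)
    age_cor <- do.call(rbind, lapply(
      list(c("prediction_error", "mean_err"), c("gain", "mean_gain")),
      function(sp) {
        v <- get(sp[2])
        pc <- partial_correlation_controlling_motion(v, age, motion)
        data.frame(measure = sp[1], partial_r = pc$r, p_value = pc$p_value,
                   n_subjects = pc$n)
      }))
    utils::write.csv(age_cor, file.path(out_dir, "age_correlations.csv"),
                     row.names = FALSE)
  }
  write_manifest(out_dir, "group",
                 config = list(gain_threshold = gain_threshold,
                               well_modeled_error = well_modeled_error,
                               alpha = alpha,
                               n_perm = n_perm, n_boot = n_boot,
                               n_subjects = length(subject_dirs)),
                 seeds = list(seed = seed),
                 timing = proc.time()[["elapsed"]] - t0)
  invisible(list(key_predictors = key, edges = edges,
                 gain_summary = gain_summary, age_correlations = age_cor))
}
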
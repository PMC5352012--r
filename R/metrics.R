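#' Normalized prediction error in percent of activity variance
#'
#' The mean squared error between predicted and observed series, divided by
#' the total mean square of the observed series about its segment mean
#' (population variance convention), times 100. Predicting the segment mean
#' at every timepoint therefore scores exactly 100% — the chance level.
#'
#' @param observed Observed activity over a segment (length >= 2,
#'   nonconstant).
#' @param predicted Model-predicted activity, same length.
#' @return Error as a percentage of the observed activity variance.
#' @examples
#' prediction_error(c(2, 0, -2, 0), c(1, 0, -1, 0))  # 25
#' @export
prediction_error <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted series differ in length")
  }
  if (length(observed) < 2L) stop("need at least 2 timepoints")
  denom <- mean((observed - mean(observed))^2)
  if (denom == 0) stop("observed series is constant (zero variance)")
  100 * mean((predicted - observed)^2) / denom
}

#' Temporal signal-to-noise ratio of an ROI time series
#'
#' Mean absolute percent signal change divided by the (population) variance
#' of the series. Low values indicate regions whose signal is dominated by
#' noise (e.g. susceptibility-artifact-prone areas).
#'
#' @param series Numeric vector, percent signal change, length >= 2.
#' @return tSNR value.
#' @examples
#' tsnr(c(1, -1, 1, -1))  # 1
#' @export
tsnr <- function(series) {
  if (length(series) < 2L) stop("need at least 2 timepoints")
  v <- mean((series - mean(series))^2)
  if (v == 0) stop("constant series (zero variance)")
  mean(abs(series)) / v
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Null distribution of test error under weight reordering
#'
#' Permutes the fitted weights across the model's own predictors (a uniform
#' random permutation per draw) and records the test-segment prediction
#' error of each permuted model. The permutation p-value uses the add-one
#' estimator `(1 + #{permuted <= observed}) / (n_perm + 1)`, so it is never
#' zero and asks whether the observed error is smaller than expected when
#' the weight-to-predictor assignment is destroyed.
#'
#' @inheritParams predict.roi_model
#' @param model A fitted `"roi_model"`.
#' @param n_perm Number of permutations (500).
#' @param seed RNG seed for reproducibility.
#' @param segment Segment on which to evaluate errors (`"test"`).
#' @return Object of class `"null_distribution"`: list with
#'   `permuted_errors`, `observed_error`, `p_value`, `n_perm`, `seed`.
#' @export
null_model_errors <- function(model, dataset, split, n_perm = 500L, seed = 1L,
                              segment = "test") {
  k <- length(model$predictors)
  if (k < 1L) stop("model has no predictors")
  rows <- segment_rows(split, segment)
  obs <- roi_column(dataset, model$target)[rows]
  x <- dataset$activity[rows, model$predictors + 1L, drop = FALSE]
  observed_error <- prediction_error(obs, drop(x %*% model$weights) +
                                       model$offset)
  permuted <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      w <- model$weights[sample.int(k)]
      prediction_error(obs, drop(x %*% w) + model$offset)
    }, numeric(1))
  })
  p <- (1 + sum(permuted <= observed_error)) / (n_perm + 1)
  structure(list(permuted_errors = permuted, observed_error = observed_error,
                 p_value = p, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Weight-permutation null: observed error %.1f%%, null %.1f +/- %.1f%% (n = %d), p = %.4g\n",
              x$observed_error, mean(x$permuted_errors),
              stats::sd(x$permuted_errors), x$n_perm, x$p_value))
  invisible(x)
}

#' Multiregional prediction gain
#'
#' The improvement in test-segment prediction accuracy of a multi-predictor
#' model over a model that uses only the single predictor ROI most
#' correlated with the target in the training data:
#' `gain = error_single - error_multi`, in percent of activity variance. A
#' large, significant gain indicates that the region's activity depends on
#' the joint integration of several regions rather than coupling to one.
#' Significance is a paired t-test over the per-timepoint squared errors of
#' the two models on the test segment.
#'
#' @inheritParams fit_ols
#' @param multi_model Multi-predictor `"roi_model"` for `target`; fit with
#'   RFE by default.
#' @param single_model Single-predictor baseline; fit with
#'   [fit_single_best_predictor()] by default.
#' @return Object of class `"gain_result"`: list with `error_multi`,
#'   `error_single`, `gain`, `p_value`, `single_predictor`,
#'   `n_predictors_multi`.
#' @export
multiregional_prediction_gain <- function(dataset, split, target,
                                          multi_model = NULL,
                                          single_model = NULL) {
  target <- resolve_roi(dataset, target)
  if (is.null(multi_model)) {
    multi_model <- fit_roi_model(dataset, target, "rfe", split)
  }
  if (is.null(single_model)) {
    single_model <- fit_single_best_predictor(dataset, split, target)
  }
  if (multi_model$target != target || single_model$target != target) {
    stop("models target different ROIs")
  }
  rows <- segment_rows(split, "test")
  obs <- roi_column(dataset, target)[rows]
  se_multi <- (obs - predict(multi_model, dataset, split, "test"))^2
  se_single <- (obs - predict(single_model, dataset, split, "test"))^2
  denom <- mean((obs - mean(obs))^2)
  error_multi <- 100 * mean(se_multi) / denom
  error_single <- 100 * mean(se_single) / denom
  d <- se_single - se_multi
  p <- if (all(abs(d) < .Machine$double.eps^0.5) || stats::sd(d) == 0) {
    1
  } else {
    stats::t.test(se_single, se_multi, paired = TRUE)$p.value
  }
  structure(list(error_multi = error_multi, error_single = error_single,
                 gain = error_single - error_multi, p_value = p,
                 single_predictor = single_model$predictors[1L],
                 n_predictors_multi = length(multi_model$predictors)),
            class = "gain_result")
}

#' @export
print.gain_result <- function(x, ...) {
  cat(sprintf("Multiregional prediction gain: %.1f%% (multi %.1f%% with %d predictors vs single %.1f%%), p = %.3g\n",
              x$gain, x$error_multi, x$n_predictors_multi, x$error_single,
              x$p_value))
  invisible(x)
}
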
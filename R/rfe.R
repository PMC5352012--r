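#' Recursive feature elimination for one target ROI
#'
#' Starts from the full predictor set (every ROI except the target), fits the
#' weighted-sum model by OLS on the training segment, and repeatedly removes
#' the predictor with the smallest absolute weight on the
#' training-standardized scale, refitting after each removal, until a single
#' predictor remains. The validation-segment prediction error of every
#' intermediate model is recorded. Ties in the smallest weight are broken
#' toward the lowest ROI id.
#'
#' @inheritParams fit_ols
#' @return An object of class `"rfe_trace"`: list with `models` (one
#'   `"roi_model"` per step, predictor counts R-1 down to 1), `val_errors`,
#'   `n_predictors`, `eliminated` (0-based ids removed after each step,
#'   length R-2), `survivor` (the final remaining predictor id), and
#'   `target`.
#' @seealso [select_final_rfe()], [select_final_rfe2()], [plot.rfe_trace()]
#' @export
run_rfe <- function(dataset, split, target) {
  target <- resolve_roi(dataset, target)
  R <- n_rois(dataset)
  if (R < 3L) stop("RFE needs at least 3 ROIs")
  current <- setdiff(seq_len(R) - 1L, target)
  obs_val <- roi_column(dataset, target)[segment_rows(split, "validation")]
  models <- vector("list", R - 1L)
  val_errors <- numeric(R - 1L)
  eliminated <- integer(R - 2L)
  for (step in seq_len(R - 1L)) {
    m <- fit_ols(dataset, split, target, current)
    models[[step]] <- m
    val_errors[step] <- m$validation_error
    if (length(current) > 1L) {
      # order() breaks |weight| ties by position; predictors are kept in
      # ascending id order, so the tied predictor with lowest id goes first
      drop_idx <- order(abs(m$std_weights), m$predictors)[1L]
      eliminated[step] <- m$predictors[drop_idx]
      current <- setdiff(current, eliminated[step])
    }
  }
  structure(list(models = models, val_errors = val_errors,
                 n_predictors = rev(seq_len(R - 1L)),
                 eliminated = eliminated, survivor = current,
                 target = target),
            class = "rfe_trace")
}

#' @export
print.rfe_trace <- function(x, ...) {
  cat(sprintf("RFE trace for target %d: %d steps (%d -> 1 predictors)\n",
              x$target, length(x$models), x$n_predictors[1]))
  cat(sprintf("  validation error: %.1f%% (full set) .. %.1f%% (min) .. %.1f%% (last)\n",
              x$val_errors[1], min(x$val_errors),
              x$val_errors[length(x$val_errors)]))
  invisible(x)
}

#' Plot the validation-error curve of an RFE trace
#'
#' Validation error (percent of activity variance) against the number of
#' predictors in the model, with the steps kept by the suffix-minimum rule
#' highlighted.
#'
#' @param x An [run_rfe()] trace.
#' @param ... Passed to [plot()].
#' @export
plot.rfe_trace <- function(x, ...) {
  kept <- kept_steps(x)
  plot(x$n_predictors, x$val_errors, type = "b", pch = 16, cex = 0.6,
       xlab = "number of predictor ROIs",
       ylab = "validation error (% of activity variance)",
       xlim = rev(range(x$n_predictors)), ...)
  points(x$n_predictors[kept], x$val_errors[kept], col = "magenta", pch = 16)
  invisible(x)
}

# Steps whose elimination strictly raised the smallest validation error over
# all later steps (the suffix-minimum rule). Applies to steps 1..(K-1); the
# last step has no suffix.
kept_steps <- function(trace) {
  v <- trace$val_errors
  K <- length(v)
  if (K < 2L) return(integer(0))
  suffix_min <- rev(cummin(rev(v)))       # suffix_min[t] = min(v[t..K])
  which(v[seq_len(K - 1L)] < suffix_min[seq.int(2L, K)])
}

#' Final RFE model: keep predictors whose elimination raised the error floor
#'
#' A predictor eliminated after step `t` is kept if and only if the
#' validation error at step `t` was strictly below the smallest validation
#' error over all later steps — i.e. its removal permanently raised the best
#' error attainable afterwards. The final surviving predictor is always
#' kept. The kept set is then refit by OLS on the training segment as the
#' final model.
#'
#' @param trace An [run_rfe()] trace.
#' @inheritParams fit_ols
#' @return A `"roi_model"` (OLS refit of the kept predictor set).
#' @export
select_final_rfe <- function(trace, dataset, split) {
  kept <- trace$eliminated[kept_steps(trace)]
  predictors <- sort(unique(c(kept, trace$survivor)))
  m <- fit_ols(dataset, split, trace$target, predictors)
  m$selection <- "rfe"
  m
}

#' Final RFE2 model: minimum of the validation-error curve
#'
#' Returns the stored model at the step with the smallest validation error
#' (no refit). Ties are resolved toward the later step, i.e. fewer
#' predictors.
#'
#' @param trace An [run_rfe()] trace.
#' @return The stored `"roi_model"` at the validation-error minimum.
#' @export
select_final_rfe2 <- function(trace) {
  v <- trace$val_errors
  best <- max(which(v == min(v)))
  m <- trace$models[[best]]
  m$selection <- "rfe2"
  m
}

#' Unselected baseline: OLS on the full predictor set
#'
#' Fits all R-1 candidate predictors by ordinary least squares with no
#' feature selection (identical to the first RFE step).
#'
#' @inheritParams fit_ols
#' @return A `"roi_model"` with all R-1 predictors.
#' @export
fit_simple_regression <- function(dataset, split, target) {
  target <- resolve_roi(dataset, target)
  if (n_rois(dataset) < 2L) stop("need at least 2 ROIs")
  fit_ols(dataset, split, target,
          setdiff(seq_len(n_rois(dataset)) - 1L, target))
}

#' Fit a sparse linear model for one target ROI
#'
#' Front-end over the package's model-selection methods. The time series is
#' split into training (first half), validation (third quarter) and test
#' (last quarter) segments; models are fit on the training segment and, for
#' the selecting methods, chosen by validation-segment prediction error.
#'
#' Methods:
#' * `"rfe"` — recursive feature elimination with the suffix-minimum
#'   final-model rule ([run_rfe()] + [select_final_rfe()]); the trace is
#'   attached as `$trace`.
#' * `"rfe2"` — RFE with the validation-curve-minimum rule.
#' * `"lasso"` — L1 path selected by validation error ([fit_lasso_path()]).
#' * `"enet"` — elastic-net grid ([fit_elastic_net_grid()]).
#' * `"simple"` — OLS on all candidates, no selection.
#' * `"single"` — the single best-correlated predictor
#'   ([fit_single_best_predictor()]).
#'
#' @inheritParams fit_ols
#' @param method Model-selection method (see Details).
#' @param config A [fit_config()] for the regularized methods.
#' @param keep_trace For the RFE methods, attach the full elimination trace.
#' @return A `"roi_model"`.
#' @examples
#' gt <- make_scenario(n_rois = 12, k_predictors = 3, seed = 1)
#' ds <- simulate_dataset(gt, n_timepoints = 200, seed = 2)
#' m <- fit_roi_model(ds, target = gt$integrators[1], method = "rfe")
#' summary(m)
#' @export
fit_roi_model <- function(dataset, target,
                          method = c("rfe", "rfe2", "lasso", "enet",
                                     "simple", "single"),
                          split = split_segments(n_timepoints(dataset)),
                          config = fit_config(), keep_trace = FALSE) {
  method <- match.arg(method)
  target <- resolve_roi(dataset, target)
  m <- switch(method,
    rfe = {
      trace <- run_rfe(dataset, split, target)
      out <- select_final_rfe(trace, dataset, split)
      if (keep_trace) out$trace <- trace
      out
    },
    rfe2 = {
      trace <- run_rfe(dataset, split, target)
      out <- select_final_rfe2(trace)
      if (keep_trace) out$trace <- trace
      out
    },
    lasso = fit_lasso_path(dataset, split, target, config),
    enet = fit_elastic_net_grid(dataset, split, target, config),
    simple = fit_simple_regression(dataset, split, target),
    single = fit_single_best_predictor(dataset, split, target)
  )
  m$method <- method
  m
}
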
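#' Construct a linear ROI model object
#'
#' A fitted (or hand-specified) linear model for one target ROI: the target's
#' activity is expressed as a weighted sum of other ROIs' activities,
#' `y_i[t] = sum_j w_ji x_j[t]`, with no intercept and no autoregressive self
#' term. Normally created by [fit_roi_model()] or one of the `fit_*`
#' functions rather than directly.
#'
#' @param target 0-based ROI id of the modeled ROI.
#' @param predictors Integer vector of 0-based predictor ROI ids (never
#'   containing `target`).
#' @param weights Numeric vector of predictor weights on the percent
#'   signal-change scale, aligned with `predictors`.
#' @param fit_method One of `"ols"`, `"lasso"`, `"elastic_net"`,
#'   `"single_predictor"`.
#' @param std_weights Weights on the training-standardized scale (used by the
#'   elimination rule); defaults to `weights`.
#' @param offset Scalar added to predictions; produced by training-segment
#'   centering of the fit (zero for hand-built models).
#' @param validation_error Validation-segment prediction error (percent of
#'   activity variance), if known.
#' @param labels Optional character labels aligned with `predictors`.
#' @param target_label Optional label of the target ROI.
#' @param extra Named list of additional fields (e.g. regularization used).
#' @return Object of class `"roi_model"`.
#' @export
new_roi_model <- function(target, predictors, weights,
                          fit_method = c("ols", "lasso", "elastic_net",
                                         "single_predictor"),
                          std_weights = weights, offset = 0,
                          validation_error = NA_real_, labels = NULL,
                          target_label = NULL, extra = list()) {
  fit_method <- match.arg(fit_method)
  predictors <- as.integer(predictors)
  if (length(predictors) < 1L) stop("model needs at least one predictor")
  if (length(weights) != length(predictors)) {
    stop("weights and predictors differ in length")
  }
  if (target %in% predictors) stop("target ROI cannot be its own predictor")
  if (anyDuplicated(predictors)) stop("duplicate predictor ids")
  out <- c(list(target = as.integer(target), predictors = predictors,
                weights = as.numeric(weights),
                std_weights = as.numeric(std_weights),
                offset = as.numeric(offset), fit_method = fit_method,
                validation_error = validation_error, labels = labels,
                target_label = target_label),
           extra)
  class(out) <- "roi_model"
  out
}

#' @export
print.roi_model <- function(x, ...) {
  tgt <- if (!is.null(x$target_label)) x$target_label else x$target
  how <- x$selection
  if (is.null(how)) how <- x$method
  if (is.null(how)) how <- x$fit_method
  cat(sprintf("Linear ROI model for target %s (%s): %d predictor(s)\n",
              tgt, how, length(x$predictors)))
  if (!is.na(x$validation_error)) {
    cat(sprintf("  validation error: %.1f%% of activity variance\n",
                x$validation_error))
  }
  invisible(x)
}

#' @export
summary.roi_model <- function(object, ...) {
  w <- object$weights
  tab <- data.frame(
    predictor = object$predictors,
    label = if (!is.null(object$labels)) object$labels else NA_character_,
    weight = w,
    weight_pct = 100 * abs(w) / sum(abs(w)),
    row.names = NULL
  )
  tab <- tab[order(-abs(tab$weight)), ]
  out <- list(model = object, weights = tab)
  class(out) <- "summary.roi_model"
  out
}

#' @export
print.summary.roi_model <- function(x, ...) {
  print(x$model)
  cat("Weights (sorted by magnitude; weight_pct = % of total absolute weight):\n")
  print(x$weights, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.roi_model <- function(object, ...) {
  w <- object$weights
  names(w) <- if (!is.null(object$labels)) object$labels else
    as.character(object$predictors)
  w
}

#' Predict a target ROI's activity from a fitted model
#'
#' Computes the weighted sum of the predictor ROIs' observed activities over
#' the rows of one segment (plus the model's centering offset, which is zero
#' for hand-built models).
#'
#' @param object An [new_roi_model()] / [fit_roi_model()] object.
#' @param dataset The [roi_dataset()] to predict from.
#' @param split A [split_segments()] object; defaults to the canonical split
#'   of the dataset's length.
#' @param segment Which segment to predict (`"test"` by default).
#' @param ... Unused.
#' @return Numeric vector of predicted activity over the segment's rows.
#' @export
predict.roi_model <- function(object, dataset,
                              split = split_segments(n_timepoints(dataset)),
                              segment = c("test", "validation", "train", "all"),
                              ...) {
  segment <- match.arg(segment)
  if (any(object$predictors >= n_rois(dataset))) {
    stop("model predictor id(s) absent from dataset")
  }
  rows <- segment_rows(split, segment)
  x <- dataset$activity[rows, object$predictors + 1L, drop = FALSE]
  drop(x %*% object$weights) + object$offset
}

#' @export
residuals.roi_model <- function(object, dataset,
                                split = split_segments(n_timepoints(dataset)),
                                segment = c("train", "validation", "test",
                                            "all"), ...) {
  segment <- match.arg(segment)
  obs <- roi_column(dataset, object$target)[segment_rows(split, segment)]
  obs - predict(object, dataset, split, segment)
}

# Training-segment standardization shared by all fitting routines: columns
# are centered by their training mean and predictors scaled by their training
# sd. Returned weights are mapped back to the percent signal-change scale;
# the centering induces a scalar offset carried by the model.
standardize_training <- function(dataset, split, target, predictors) {
  tr_rows <- segment_rows(split, "train")
  xm <- dataset$activity[, predictors + 1L, drop = FALSE]
  y <- roi_column(dataset, target)
  mu_x <- colMeans(xm[tr_rows, , drop = FALSE])
  mu_y <- mean(y[tr_rows])
  sd_x <- apply(xm[tr_rows, , drop = FALSE], 2L, stats::sd)
  if (any(sd_x == 0)) {
    stop("constant training column for predictor id(s) ",
         paste(predictors[sd_x == 0], collapse = ", "))
  }
  xs <- sweep(sweep(xm, 2L, mu_x, "-"), 2L, sd_x, "/")
  list(x_train = xs[tr_rows, , drop = FALSE], y_train = y[tr_rows] - mu_y,
       x_all = xs, y = y, mu_x = mu_x, mu_y = mu_y, sd_x = sd_x,
       tr_rows = tr_rows)
}

# Map standardized-scale weights back to a model object.
finish_model <- function(dataset, split, target, predictors, w_std,
                         fit_method, drop_zero = FALSE, std, extra = list()) {
  keep <- if (drop_zero) which(w_std != 0) else seq_along(w_std)
  if (length(keep) == 0L) stop("model reduced to the empty predictor set")
  predictors <- predictors[keep]
  w_std <- w_std[keep]
  w <- w_std / std$sd_x[keep]
  offset <- std$mu_y - sum(w * std$mu_x[keep])
  m <- new_roi_model(target, predictors, w, fit_method,
                     std_weights = w_std, offset = offset,
                     labels = dataset$parcels$label_hemi[predictors + 1L],
                     target_label = dataset$parcels$label_hemi[target + 1L],
                     extra = extra)
  m$validation_error <- prediction_error(
    roi_column(dataset, target)[segment_rows(split, "validation")],
    predict(m, dataset, split, "validation"))
  m
}

#' Ordinary least-squares fit of a target ROI on a given predictor set
#'
#' Minimizes the training-segment sum of squared residuals of the
#' intercept-free weighted-sum model. When the system is underdetermined
#' (more predictors than training rows) the minimum-norm solution is returned
#' with a warning.
#'
#' @inheritParams predict.roi_model
#' @param target 0-based id (or label) of the modeled ROI.
#' @param predictors Integer vector of 0-based predictor ids.
#' @return A `"roi_model"` with `fit_method = "ols"`.
#' @export
fit_ols <- function(dataset, split, target, predictors) {
  target <- resolve_roi(dataset, target)
  predictors <- as.integer(predictors)
  if (length(predictors) == 0L) stop("empty predictor list")
  if (target %in% predictors) stop("target ROI cannot be its own predictor")
  std <- standardize_training(dataset, split, target, predictors)
  x <- std$x_train
  y <- std$y_train
  if (nrow(x) >= ncol(x)) {
    qr_x <- qr(x)
    if (qr_x$rank < ncol(x)) {
      w_std <- pinv_solve(x, y)
    } else {
      w_std <- qr.coef(qr_x, y)
    }
  } else {
    warning("underdetermined OLS (", ncol(x), " predictors, ", nrow(x),
            " training rows): returning the minimum-norm solution")
    w_std <- pinv_solve(x, y)
  }
  finish_model(dataset, split, target, predictors, w_std, "ols", std = std)
}

# Minimum-norm least-squares via SVD pseudoinverse.
pinv_solve <- function(x, y) {
  sv <- svd(x)
  tol <- max(dim(x)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
}

#' Baseline model from the single best-correlated predictor
#'
#' Selects the candidate ROI whose training-segment activity has the largest
#' absolute Pearson correlation with the target, then OLS-fits that single
#' predictor. Exact correlation ties are broken toward the lowest ROI id.
#'
#' @inheritParams fit_ols
#' @return A `"roi_model"` with `fit_method = "single_predictor"`.
#' @export
fit_single_best_predictor <- function(dataset, split, target) {
  target <- resolve_roi(dataset, target)
  if (n_rois(dataset) < 2L) stop("need at least 2 ROIs")
  tr_rows <- segment_rows(split, "train")
  y <- roi_column(dataset, target)[tr_rows]
  cand <- setdiff(seq_len(n_rois(dataset)) - 1L, target)
  cors <- vapply(cand, function(j) {
    xj <- dataset$activity[tr_rows, j + 1L]
    if (stats::sd(xj) == 0 || stats::sd(y) == 0) NA_real_
    else abs(stats::cor(xj, y))
  }, numeric(1))
  if (all(is.na(cors))) stop("all candidate correlations are undefined")
  best <- cand[which.max(cors)]  # which.max takes the first (lowest id) on ties
  m <- fit_ols(dataset, split, target, best)
  m$fit_method <- "single_predictor"
  m
}
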
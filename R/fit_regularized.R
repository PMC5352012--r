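#' Regularization-grid configuration
#'
#' Settings for the Lasso path and the elastic-net grid. The penalized
#' objective is `mean((y - yhat)^2) + c * [mix * |w|_1 + (1 - mix)/2 * |w|_2^2]`
#' with `mix = 1` for the Lasso; `c` runs over a log-spaced grid from `c_max`
#' (the smallest magnitude at which the solution is entirely zero) down to
#' `c_max * lambda_min_ratio`.
#'
#' @param n_lasso_lambdas Number of Lasso regularization magnitudes (200).
#' @param n_enet_lambdas Magnitudes per elastic-net mix (50).
#' @param enet_mixes L1-vs-L2 mixing proportions in (0, 1]
#'   (0.01, 0.05, 0.1, 0.5, 1 — a 250-candidate grid).
#' @param lambda_min_ratio Ratio of the smallest to the largest magnitude.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(n_lasso_lambdas = 200L, n_enet_lambdas = 50L,
                       enet_mixes = c(0.01, 0.05, 0.1, 0.5, 1),
                       lambda_min_ratio = 1e-4) {
  stopifnot(n_lasso_lambdas >= 1L, n_enet_lambdas >= 1L,
            length(enet_mixes) >= 1L, all(enet_mixes > 0),
            all(enet_mixes <= 1), lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(n_lasso_lambdas = as.integer(n_lasso_lambdas),
                 n_enet_lambdas = as.integer(n_enet_lambdas),
                 enet_mixes = enet_mixes,
                 lambda_min_ratio = lambda_min_ratio),
            class = "fit_config")
}

# Solve the penalized regression at each magnitude of a log-spaced grid for
# one mix value, on the training-standardized scale. Returns the grid `c`,
# the standardized weight matrix (p x n_c) and the validation error of every
# candidate. glmnet's objective is 1/(2n)*RSS + lambda*(alpha|w|1 +
# (1-alpha)/2 |w|2^2); multiplying by two maps it onto the objective above
# with c = 2*lambda and mix = alpha.
penalized_path <- function(dataset, split, target, predictors, mix, n_c,
                           lambda_min_ratio) {
  std <- standardize_training(dataset, split, target, predictors)
  x <- std$x_train
  y <- std$y_train
  n <- nrow(x)
  c_max_l1 <- 2 * max(abs(crossprod(x, y))) / n   # all-zero threshold, mix = 1
  c_max <- c_max_l1 / mix
  c_grid <- exp(seq(log(c_max), log(c_max * lambda_min_ratio),
                    length.out = n_c))
  x_fit <- if (ncol(x) == 1L) cbind(x, 0) else x  # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(x_fit, y, family = "gaussian", alpha = mix,
                        lambda = c_grid / 2, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-16, maxit = 1e6)
  w <- as.matrix(fit$beta)[seq_len(ncol(x)), , drop = FALSE]
  w[abs(w) < 1e-10] <- 0  # coordinate-descent dust, not active predictors
  if (ncol(w) < length(c_grid)) {  # glmnet may drop unconverged tail lambdas
    c_grid <- c_grid[seq_len(ncol(w))]
  }
  val_rows <- segment_rows(split, "validation")
  y_val <- std$y[val_rows]
  w_orig <- w / std$sd_x
  offs <- std$mu_y - drop(crossprod(w_orig, std$mu_x))
  pred <- sweep(dataset$activity[val_rows, predictors + 1L, drop = FALSE] %*%
                  w_orig, 2L, offs, "+")
  verr <- apply(pred, 2L, function(p) prediction_error(y_val, p))
  list(c_grid = c_grid, weights = w, val_errors = verr, std = std,
       predictors = predictors)
}

# Pick the best candidate column: smallest validation error; ties prefer
# fewer nonzero predictors, then larger c (earlier grid position).
select_path_candidate <- function(path) {
  verr <- path$val_errors
  nz <- colSums(path$weights != 0)
  ord <- order(verr, nz, seq_along(verr))
  ord[1L]
}

#' Lasso model selected by validation error over a regularization path
#'
#' Fits the L1-penalized weighted-sum model at 200 (by default) log-spaced
#' regularization magnitudes on the training segment, evaluates every
#' candidate's prediction error on the validation segment, and returns the
#' candidate with the smallest validation error with its zero-weight
#' predictors dropped. Validation-error ties prefer the sparser candidate,
#' then the stronger penalty.
#'
#' @inheritParams fit_ols
#' @param config A [fit_config()].
#' @return A `"roi_model"` with `fit_method = "lasso"`; the chosen
#'   regularization magnitude is stored in `$reg_c`.
#' @export
fit_lasso_path <- function(dataset, split, target, config = fit_config()) {
  target <- resolve_roi(dataset, target)
  predictors <- setdiff(seq_len(n_rois(dataset)) - 1L, target)
  path <- penalized_path(dataset, split, target, predictors, mix = 1,
                         n_c = config$n_lasso_lambdas,
                         lambda_min_ratio = config$lambda_min_ratio)
  best <- select_path_candidate(path)
  w_std <- path$weights[, best]
  if (all(w_std == 0)) {
    stop("no informative predictor at any regularization magnitude")
  }
  finish_model(dataset, split, target, predictors, w_std, "lasso",
               drop_zero = TRUE, std = path$std,
               extra = list(reg_c = path$c_grid[best], reg_mix = 1))
}

#' Elastic-net model selected by validation error over a two-parameter grid
#'
#' As [fit_lasso_path()], but the candidates span 50 regularization
#' magnitudes for each of 5 L1-vs-L2 mixing proportions (250 candidates by
#' default). The additional L2 term spreads weight over groups of correlated
#' predictors instead of picking one representative.
#'
#' @inheritParams fit_lasso_path
#' @return A `"roi_model"` with `fit_method = "elastic_net"`; `$reg_c` and
#'   `$reg_mix` record the chosen grid point.
#' @export
fit_elastic_net_grid <- function(dataset, split, target,
                                 config = fit_config()) {
  target <- resolve_roi(dataset, target)
  predictors <- setdiff(seq_len(n_rois(dataset)) - 1L, target)
  best <- NULL
  for (mix in config$enet_mixes) {
    path <- penalized_path(dataset, split, target, predictors, mix = mix,
                           n_c = config$n_enet_lambdas,
                           lambda_min_ratio = config$lambda_min_ratio)
    i <- select_path_candidate(path)
    cand <- list(verr = path$val_errors[i],
                 nz = sum(path$weights[, i] != 0),
                 w_std = path$weights[, i], c = path$c_grid[i], mix = mix,
                 std = path$std)
    if (is.null(best) ||
        cand$verr < best$verr ||
        (cand$verr == best$verr && cand$nz < best$nz) ||
        (cand$verr == best$verr && cand$nz == best$nz && cand$c > best$c)) {
      best <- cand
    }
  }
  if (all(best$w_std == 0)) {
    stop("no informative predictor at any regularization magnitude")
  }
  finish_model(dataset, split, target, predictors, best$w_std, "elastic_net",
               drop_zero = TRUE, std = best$std,
               extra = list(reg_c = best$c, reg_mix = best$mix))
}
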
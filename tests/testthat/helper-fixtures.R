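# Shared fixtures and independent oracles for the test suite.

# Minimal parcel table for R ROIs: unpaired parcels on a line.
toy_parcels <- function(R) {
  data.frame(label = sprintf("p%02d", seq_len(R) - 1L),
             hemisphere = "none",
             x_mm = 10 * (seq_len(R) - 1L), y_mm = 0, z_mm = 0,
             voxel_count = 100L)
}

# Wrap a raw activity matrix (columns are mean-centered here) as a dataset.
toy_dataset <- function(activity, parcels = toy_parcels(ncol(activity))) {
  activity <- sweep(activity, 2L, colMeans(activity), "-")
  roi_dataset(activity, parcels,
              meta = list(subject_id = "toy", age_years = 30,
                          head_motion_mm = 0.1))
}

# Random zero-mean dataset, T x R, seeded.
random_dataset <- function(T, R, seed = 1) {
  set.seed(seed)
  toy_dataset(matrix(rnorm(T * R), T, R))
}

# Independent OLS oracle: normal equations on the training-centered system
# (the model's centering by training means is part of its contract).
ols_oracle <- function(dataset, split, target, predictors) {
  tr <- segment_rows(split, "train")
  x <- dataset$activity[tr, predictors + 1L, drop = FALSE]
  y <- dataset$activity[tr, target + 1L]
  xc <- sweep(x, 2L, colMeans(x), "-")
  yc <- y - mean(y)
  drop(solve(t(xc) %*% xc, t(xc) %*% yc))
}

# Independent KKT subgradient check for the penalized objective
# mean((y - Xw)^2) + c * [mix|w|_1 + (1-mix)/2 |w|_2^2] on the standardized
# training system. Returns the worst violation over coordinates.
kkt_violation <- function(x, y, w, c, mix = 1) {
  n <- nrow(x)
  g <- -(2 / n) * drop(crossprod(x, y - x %*% w)) + c * (1 - mix) * w
  viol <- numeric(length(w))
  active <- w != 0
  viol[active] <- abs(g[active] + c * mix * sign(w[active]))
  viol[!active] <- pmax(0, abs(g[!active]) - c * mix)
  max(viol)
}

# Standardized training system exactly as the fitting code constructs it.
standardized_system <- function(dataset, split, target, predictors) {
  tr <- segment_rows(split, "train")
  x <- dataset$activity[tr, predictors + 1L, drop = FALSE]
  y <- dataset$activity[tr, target + 1L]
  xc <- sweep(x, 2L, colMeans(x), "-")
  xs <- sweep(xc, 2L, apply(x, 2L, sd), "/")
  list(x = xs, y = y - mean(y))
}

# Fake RFE trace with a prescribed validation curve; predictor ids are
# 0..(K-1) eliminated in order, with id K the survivor.
fake_trace <- function(val_errors, target = 99L) {
  K <- length(val_errors)
  eliminated <- seq_len(K - 1L) - 1L
  survivor <- K - 1L
  models <- lapply(seq_len(K), function(t) {
    preds <- c(eliminated[seq.int(t, length.out = max(0L, K - t))], survivor)
    new_roi_model(target, preds, rep(1, length(preds)))
  })
  structure(list(models = models, val_errors = val_errors,
                 n_predictors = rev(seq_len(K)), eliminated = eliminated,
                 survivor = survivor, target = target),
            class = "rfe_trace")
}

# Default study-scale scenario shared by the recovery tests.
recovery_scenario <- function(seed = 1) make_scenario(seed = seed)
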
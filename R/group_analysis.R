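#' Normalize model weights to percent of total absolute weight
#'
#' Each predictor's coefficient is expressed as its absolute value divided by
#' the sum of absolute weights onto the modeled ROI, times 100, so weights
#' are comparable within and across models. The entries sum to 100.
#'
#' @param model A `"roi_model"`, or a bare numeric weight vector.
#' @return Numeric vector of weights in percent, aligned with the model's
#'   predictors.
#' @examples
#' normalize_weights(c(2, -1, 1))  # 50 25 25
#' @export
normalize_weights <- function(model) {
  w <- if (inherits(model, "roi_model")) model$weights else as.numeric(model)
  tot <- sum(abs(w))
  if (tot == 0) stop("all weights are zero; normalization undefined")
  100 * abs(w) / tot
}

#' Bootstrap mean and percentile confidence interval
#'
#' Resamples the values with replacement `n_boot` times and returns the
#' bootstrap estimate of the mean with the percentile 95% confidence
#' interval of the bootstrap means.
#'
#' @param values Non-empty numeric vector.
#' @param n_boot Number of bootstrap resamples (500).
#' @param seed RNG seed.
#' @param conf Confidence level (0.95).
#' @return List with `mean`, `ci` (length-2 vector), `n_boot`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 500L, seed = 1L, conf = 0.95) {
  values <- as.numeric(values)
  n <- length(values)
  if (n == 0L) stop("empty input")
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) mean(values[sample.int(n, replace = TRUE)]),
           numeric(1))
  })
  a <- (1 - conf) / 2
  list(mean = mean(boots),
       ci = unname(stats::quantile(boots, c(a, 1 - a), type = 7)),
       n_boot = as.integer(n_boot))
}

# Null normalized weights for one subject's model: the model's absolute
# weights are placed on a uniformly random subset of the candidate
# predictors (zeros elsewhere) and normalized. Destroying the
# weight-to-region assignment over the whole candidate set gives every
# candidate a well-defined null, against which "significantly large weight"
# is testable.
null_normalized_weights <- function(abs_weights, candidates, n_perm) {
  k <- length(abs_weights)
  wn <- 100 * abs_weights / sum(abs_weights)
  out <- matrix(0, nrow = n_perm, ncol = length(candidates),
                dimnames = list(NULL, as.character(candidates)))
  for (i in seq_len(n_perm)) {
    pos <- sample.int(length(candidates), k)
    out[i, pos] <- wn[sample.int(k)]
  }
  out
}

#' Identify key predictor ROIs across subjects
#'
#' For one target ROI, pools each subject's fitted model and tests, for every
#' candidate predictor, whether its normalized weight (percent of the total
#' absolute weight onto the target; zero when the predictor is absent from a
#' subject's model) is significantly larger across subjects than under null
#' models in which each subject's weights are reassigned to random candidate
#' ROIs. The one-sided Welch t-test p-value is Bonferroni-corrected by
#' multiplying by the number of comparisons and capping at 1. Bootstrap mean
#' and 95% CI of the observed normalized weights are attached.
#'
#' @param models List of `"roi_model"` objects for the same target, one per
#'   subject (at least 2).
#' @param n_rois Total number of ROIs (candidates are all ids except the
#'   target).
#' @param n_perm Null reassignments per subject (200).
#' @param alpha Significance level applied to the corrected p-value (0.05).
#' @param n_comparisons Bonferroni multiplier; defaults to the number of
#'   candidate predictors.
#' @param n_boot Bootstrap resamples for the mean/CI (500).
#' @param seed RNG seed.
#' @return Data frame (one row per candidate): `target`, `predictor`,
#'   `mean_weight_pct`, `ci_low`, `ci_high`, `p_corrected`, `key`.
#' @export
identify_key_predictors <- function(models, n_rois, n_perm = 200L,
                                    alpha = 0.05, n_comparisons = NULL,
                                    n_boot = 500L, seed = 1L) {
  if (length(models) < 2L) stop("need at least 2 subjects")
  target <- models[[1L]]$target
  if (!all(vapply(models, function(m) m$target, integer(1)) == target)) {
    stop("models target different ROIs")
  }
  candidates <- setdiff(seq_len(n_rois) - 1L, target)
  if (is.null(n_comparisons)) n_comparisons <- length(candidates)
  S <- length(models)
  obs <- matrix(0, nrow = S, ncol = length(candidates),
                dimnames = list(NULL, as.character(candidates)))
  for (s in seq_len(S)) {
    wn <- normalize_weights(models[[s]])
    obs[s, as.character(models[[s]]$predictors)] <- wn
  }
  # each subject's null draws are seeded from its own weights, so the pooled
  # null (and hence the whole analysis) is invariant to subject ordering
  null_mat <- do.call(rbind, lapply(models, function(m) {
    sub_seed <- (seed + round(sum(abs(m$weights)) * 1e6)) %% 2147483647
    with_seed(sub_seed, {
      null_normalized_weights(abs(m$weights), candidates, n_perm)
    })
  }))
  res <- lapply(seq_along(candidates), function(j) {
    o <- obs[, j]
    nu <- null_mat[, j]
    p_raw <- if (all(o == 0)) {
      1  # predictor absent from every subject's model: never key
    } else if (stats::sd(o) == 0 && stats::sd(nu) == 0) {
      if (mean(o) > mean(nu)) 0 else 1
    } else {
      stats::t.test(o, nu, alternative = "greater")$p.value
    }
    bs <- bootstrap_mean_ci(sort(o), n_boot = n_boot, seed = seed + j)
    data.frame(target = target, predictor = candidates[j],
               mean_weight_pct = bs$mean, ci_low = bs$ci[1],
               ci_high = bs$ci[2],
               p_corrected = min(1, p_raw * n_comparisons))
  })
  out <- do.call(rbind, res)
  out$key <- out$p_corrected < alpha
  rownames(out) <- NULL
  out
}

#' Classify interregional dependencies by distance and hemisphere
#'
#' Computes the Euclidean distance between parcel centroids for each
#' (target, predictor) edge and labels it short (<= 50 mm) or long (> 50 mm),
#' homotopic (same label, opposite hemisphere) and/or interhemispheric.
#'
#' @param edges Data frame with integer columns `target` and `predictor`
#'   (0-based ROI ids).
#' @param parcels Parcel table from an [roi_dataset()].
#' @param long_threshold_mm Distance separating short from long dependencies
#'   (50 mm).
#' @return The edge data frame with added `distance_mm`, `kind`, `homotopic`,
#'   `interhemispheric`.
#' @export
classify_dependencies <- function(edges, parcels, long_threshold_mm = 50) {
  edges <- as.data.frame(edges)
  cent <- as.matrix(parcels[, c("x_mm", "y_mm", "z_mm")])
  if (anyNA(cent)) stop("missing centroid coordinates in parcel table")
  i <- match(edges$target, parcels$roi_id)
  j <- match(edges$predictor, parcels$roi_id)
  if (anyNA(i) || anyNA(j)) stop("edge references unknown ROI id")
  edges$distance_mm <- sqrt(rowSums((cent[i, , drop = FALSE] -
                                       cent[j, , drop = FALSE])^2))
  edges$kind <- ifelse(edges$distance_mm > long_threshold_mm, "long", "short")
  hi <- parcels$hemisphere[i]
  hj <- parcels$hemisphere[j]
  edges$interhemispheric <- hi != hj & hi != "none" & hj != "none"
  edges$homotopic <- edges$interhemispheric &
    parcels$label[i] == parcels$label[j]
  edges
}

#' Check that model weights track activity correlations
#'
#' Pools, across models, each predictor's normalized weight together with the
#' absolute training-segment Pearson correlation between that predictor and
#' its target, and reports the correlation between the two with a shuffle
#' (permutation) p-value. Well-behaved fits show a clear positive
#' relationship.
#'
#' @param models List of fitted `"roi_model"` objects.
#' @param datasets A single [roi_dataset()] shared by all models, or a list
#'   of datasets aligned with `models`.
#' @param split A [split_segments()]; defaults to the canonical split.
#' @param n_shuffle Number of shuffles of the correlation values (1000).
#' @param seed RNG seed.
#' @return List with `r`, `p_value`, `n_pairs`.
#' @export
weight_correlation_check <- function(models, datasets, split = NULL,
                                     n_shuffle = 1000L, seed = 1L) {
  if (inherits(datasets, "roi_dataset")) {
    datasets <- rep(list(datasets), length(models))
  }
  pairs <- do.call(rbind, mapply(function(m, ds) {
    sp <- if (is.null(split)) split_segments(n_timepoints(ds)) else split
    tr <- segment_rows(sp, "train")
    y <- roi_column(ds, m$target)[tr]
    rho <- vapply(m$predictors, function(j) {
      abs(stats::cor(ds$activity[tr, j + 1L], y))
    }, numeric(1))
    cbind(weight = normalize_weights(m), activity_cor = rho)
  }, models, datasets, SIMPLIFY = FALSE))
  if (nrow(pairs) < 10L) stop("need at least 10 (weight, correlation) pairs")
  w <- pairs[, "weight"]
  rho <- pairs[, "activity_cor"]
  if (stats::sd(w) == 0 || stats::sd(rho) == 0) {
    stop("degenerate (constant) weight or correlation vector")
  }
  r_obs <- stats::cor(w, rho)
  r_null <- with_seed(seed, {
    vapply(seq_len(n_shuffle), function(i) {
      stats::cor(w, rho[sample.int(length(rho))])
    }, numeric(1))
  })
  p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (n_shuffle + 1)
  list(r = r_obs, p_value = p, n_pairs = nrow(pairs))
}

#' Partial correlation with age, controlling for head motion
#'
#' Pearson correlation between a per-subject measure and age after
#' residualizing both on head motion, guarding age effects against the known
#' motion-age confound. The two-sided p-value uses the t distribution with
#' n - 3 degrees of freedom.
#'
#' @param measure Per-subject measure of interest (e.g. mean prediction
#'   error or gain).
#' @param age Subject ages in years.
#' @param motion Mean head displacement between consecutive volumes, mm.
#' @return List with `r`, `p_value`, `n`.
#' @export
partial_correlation_controlling_motion <- function(measure, age, motion) {
  n <- length(measure)
  if (length(age) != n || length(motion) != n) stop("unequal input lengths")
  if (n < 4L) stop("need at least 4 subjects")
  if (stats::sd(measure) == 0 || stats::sd(age) == 0) {
    stop("constant measure or age vector")
  }
  res_m <- stats::residuals(stats::lm(measure ~ motion))
  res_a <- stats::residuals(stats::lm(age ~ motion))
  # residuals that are numerically zero mean the covariate explains the
  # variable exactly: nothing is left to correlate
  if (stats::sd(res_m) <= 1e-10 * stats::sd(measure) ||
      stats::sd(res_a) <= 1e-10 * stats::sd(age)) {
    return(list(r = 0, p_value = 1, n = n))
  }
  r <- stats::cor(res_m, res_a)
  tt <- r * sqrt((n - 3) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 3)
  list(r = r, p_value = p, n = n)
}
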
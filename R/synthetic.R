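#' Ground-truth scenario for synthetic multiregional activity
#'
#' Builds a known sparse dependency structure emulating the features of
#' parcellated resting-state BOLD data that the modeling pipeline must cope
#' with: temporally autocorrelated signals, "integrator" regions driven by a
#' handful of other regions, a strongly coupled (redundant) region pair, and
#' a low-tSNR (high-noise) region.
#'
#' Structure, given `n_rois = R` (even; ids 0..R/2-1 are the left hemisphere,
#' their homotopic partners R/2..R-1 the right):
#' * driver ROIs: independent AR(1) processes (coefficient `ar_coef`, unit
#'   marginal variance) standing in for exogenous fluctuations;
#' * integrator ROIs (`n_integrators` of them, sampled with the structure
#'   seed): weighted sums of `k_predictors` distinct drivers plus AR(1)
#'   observation noise. Weight magnitudes are spread linearly over
#'   `[0.6, 1.4] * true_weight` with alternating signs, so `true_weight` is
#'   the mean magnitude; heterogeneous magnitudes keep weight-permutation
#'   null models informative, mirroring real fitted weights;
#' * one coupled pair: ROI 0 and its homotopic partner, with activity
#'   correlation `coupling` (emulating e.g. homotopic isthmus-cingulate
#'   coupling);
#' * one low-tSNR ROI: pure AR(1) noise at three times the driver amplitude.
#'
#' Unless given, `noise_sd` is set so the integrator observation noise is
#' one quarter of the signal variance, i.e. about 20% residual variance — the
#' error level of a well-modeled cortical region.
#'
#' @param n_rois Number of ROIs (even, >= 8).
#' @param k_predictors True predictors per integrator ROI.
#' @param true_weight Mean absolute true weight.
#' @param noise_sd Marginal sd of integrator observation noise, or `NULL`
#'   for the 20%-residual calibration.
#' @param n_integrators Number of integrator ROIs.
#' @param coupling Activity correlation of the coupled pair.
#' @param include_coupled_pair,include_low_tsnr_roi Toggle those features.
#' @param ar_coef AR(1) coefficient of all latent processes.
#' @param seed Structure seed: fixes which ROIs are integrators and which
#'   drivers they draw on.
#' @return Object of class `"roi_ground_truth"`: `n_rois`, `weight_matrix`
#'   (R x R, entry `[j+1, i+1]` is the true weight of ROI j onto ROI i),
#'   `drivers`, `integrators`, `coupled_pairs`, `low_tsnr`, `noise_sd`
#'   (per-ROI), `ar_coef`, `seed`.
#' @export
make_scenario <- function(n_rois = 32L, k_predictors = 5L, true_weight = 0.2,
                          noise_sd = NULL, n_integrators = 4L,
                          coupling = 0.85, include_coupled_pair = TRUE,
                          include_low_tsnr_roi = TRUE, ar_coef = 0.5,
                          seed = 1L) {
  n_rois <- as.integer(n_rois)
  if (n_rois < 8L || n_rois %% 2L != 0L) stop("n_rois must be even and >= 8")
  if (k_predictors >= n_rois - 1L) stop("k_predictors must be < n_rois - 1")
  reserved <- integer(0)
  coupled_pairs <- NULL
  if (include_coupled_pair) {
    coupled_pairs <- data.frame(a = 0L, b = n_rois %/% 2L, r = coupling)
    reserved <- c(reserved, 0L, n_rois %/% 2L)
  }
  low_tsnr <- integer(0)
  if (include_low_tsnr_roi) {
    low_tsnr <- n_rois - 1L
    reserved <- c(reserved, low_tsnr)
  }
  free <- setdiff(seq_len(n_rois) - 1L, reserved)
  if (length(free) < n_integrators + k_predictors) {
    stop("infeasible configuration: too few ROIs for the requested structure")
  }
  mags <- true_weight * seq(0.6, 1.4, length.out = k_predictors)
  signs <- rep_len(c(1, -1), k_predictors)
  w_true <- mags * signs
  if (is.null(noise_sd)) noise_sd <- sqrt(sum(w_true^2) / 4)
  W <- matrix(0, n_rois, n_rois)
  sd_vec <- rep(0, n_rois)
  scenario <- with_seed(seed, {
    integrators <- sort(sample(free, n_integrators))
    drivers <- setdiff(free, integrators)
    if (length(drivers) < k_predictors) {
      stop("infeasible configuration: not enough driver ROIs")
    }
    for (i in integrators) {
      src <- sample(drivers, k_predictors)
      W[src + 1L, i + 1L] <- w_true[sample.int(k_predictors)]
      sd_vec[i + 1L] <- noise_sd
    }
    list(integrators = integrators, drivers = sort(drivers), W = W,
         sd_vec = sd_vec)
  })
  if (include_coupled_pair) {
    scenario$W[1L, n_rois %/% 2L + 1L] <- coupling
  }
  structure(list(n_rois = n_rois, weight_matrix = scenario$W,
                 drivers = scenario$drivers,
                 integrators = scenario$integrators,
                 coupled_pairs = coupled_pairs, low_tsnr = low_tsnr,
                 noise_sd = scenario$sd_vec, ar_coef = ar_coef,
                 k_predictors = as.integer(k_predictors),
                 true_weight = true_weight, seed = as.integer(seed)),
            class = "roi_ground_truth")
}

#' @export
print.roi_ground_truth <- function(x, ...) {
  cat(sprintf("Synthetic ground truth: %d ROIs, %d integrator(s) with %d true predictors each\n",
              x$n_rois, length(x$integrators), x$k_predictors))
  cat("  integrators:", paste(x$integrators, collapse = ", "), "\n")
  if (!is.null(x$coupled_pairs)) {
    cat(sprintf("  coupled pair: (%d, %d) r = %.2f\n", x$coupled_pairs$a[1],
                x$coupled_pairs$b[1], x$coupled_pairs$r[1]))
  }
  if (length(x$low_tsnr) > 0) {
    cat("  low-tSNR ROI:", paste(x$low_tsnr, collapse = ", "), "\n")
  }
  invisible(x)
}

# Unit-marginal-variance AR(1) series.
ar1_series <- function(n, phi) {
  innov_sd <- sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, sd = innov_sd), phi,
                           method = "recursive",
                           init = stats::rnorm(1)))
}

#' Simulate a subject dataset from a ground-truth scenario
#'
#' Generates the latent driver series, mixes them into the integrator ROIs
#' with the true weights, adds the coupled pair and the low-tSNR region, and
#' wraps everything in an [roi_dataset()] with fabricated parcel metadata:
#' homotopic label pairs across hemispheres and centroids on a lattice
#' spanning both short (< 50 mm) and long (> 50 mm) distances. Columns are
#' exactly mean-centered (percent signal-change convention); the
#' construction scale is kept so the ground-truth weights stay exact.
#'
#' @param gt A [make_scenario()] ground truth.
#' @param n_timepoints Series length (660, about 21 minutes at TR 1.94 s).
#' @param seed Noise seed: different seeds give different activity with an
#'   identical dependency structure.
#' @param subject_id,age_years,head_motion_mm Subject metadata; by default
#'   age is drawn in 18..77 and head motion is age-correlated around
#'   0.12 mm.
#' @param tr Repetition time in seconds.
#' @return An [roi_dataset()]; the ground truth is attached as
#'   `attr(, "ground_truth")`.
#' @export
simulate_dataset <- function(gt, n_timepoints = 660L, seed = 1L,
                             subject_id = sprintf("sim%03d", seed),
                             age_years = NULL, head_motion_mm = NULL,
                             tr = 1.94) {
  stopifnot(inherits(gt, "roi_ground_truth"))
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 8L) stop("need at least 8 timepoints")
  R <- gt$n_rois
  act <- with_seed(seed, {
    a <- matrix(0, n_timepoints, R)
    for (j in gt$drivers) a[, j + 1L] <- ar1_series(n_timepoints, gt$ar_coef)
    if (!is.null(gt$coupled_pairs)) {
      pa <- gt$coupled_pairs$a[1]
      pb <- gt$coupled_pairs$b[1]
      r <- gt$coupled_pairs$r[1]
      a[, pa + 1L] <- ar1_series(n_timepoints, gt$ar_coef)
      a[, pb + 1L] <- r * a[, pa + 1L] +
        sqrt(1 - r^2) * ar1_series(n_timepoints, gt$ar_coef)
    }
    for (i in gt$integrators) {
      w <- gt$weight_matrix[, i + 1L]
      src <- which(w != 0)
      a[, i + 1L] <- a[, src, drop = FALSE] %*% w[src] +
        gt$noise_sd[i + 1L] * ar1_series(n_timepoints, gt$ar_coef)
    }
    for (j in gt$low_tsnr) a[, j + 1L] <- 3 * ar1_series(n_timepoints,
                                                         gt$ar_coef)
    meta_age <- if (is.null(age_years)) round(stats::runif(1, 18, 77)) else
      age_years
    meta_motion <- if (is.null(head_motion_mm)) {
      max(0.01, 0.04 + 0.002 * meta_age + stats::rnorm(1, 0, 0.03))
    } else head_motion_mm
    list(a = a, age = meta_age, motion = meta_motion)
  })
  activity <- sweep(act$a, 2L, colMeans(act$a), "-")
  parcels <- synthetic_parcels(R)
  meta <- list(subject_id = subject_id, age_years = act$age,
               head_motion_mm = act$motion)
  ds <- roi_dataset(activity, parcels, meta, tr = tr)
  attr(ds, "ground_truth") <- gt
  ds
}

# Fabricated parcel metadata: R/2 labels duplicated across hemispheres,
# centroids on a lattice (hemispheres at x = -35 / +35 mm; y,z on a 30 mm
# grid) so both short- and long-distance edges occur.
synthetic_parcels <- function(R) {
  half <- R %/% 2L
  idx <- seq_len(half) - 1L
  grid_side <- ceiling(sqrt(half))
  data.frame(
    label = rep(sprintf("roi_%02d", idx), 2L),
    hemisphere = rep(c("left", "right"), each = half),
    x_mm = rep(c(-35, 35), each = half),
    y_mm = rep(30 * (idx %% grid_side), 2L),
    z_mm = rep(30 * (idx %/% grid_side), 2L),
    voxel_count = rep(120L + 10L * (idx %% 5L), 2L)
  )
}

#' True predictors of a target ROI in a ground truth
#'
#' @param gt A [make_scenario()] ground truth.
#' @param target 0-based ROI id.
#' @return Sorted integer vector of 0-based true predictor ids.
#' @export
true_predictors <- function(gt, target) {
  sort(which(gt$weight_matrix[, target + 1L] != 0) - 1L)
}

#' Set-overlap metrics of a selected predictor set against the ground truth
#'
#' @param selected Integer vector of selected 0-based predictor ids.
#' @param gt A [make_scenario()] ground truth.
#' @param target 0-based id of the modeled (integrator) ROI.
#' @return List with `precision`, `recall`, `jaccard`.
#' @export
evaluate_recovery <- function(selected, gt, target) {
  truth <- true_predictors(gt, target)
  if (length(truth) == 0L) stop("target has no true predictors")
  selected <- unique(as.integer(selected))
  tp <- length(intersect(selected, truth))
  list(precision = if (length(selected) == 0L) 0 else tp / length(selected),
       recall = tp / length(truth),
       jaccard = tp / length(union(selected, truth)))
}
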
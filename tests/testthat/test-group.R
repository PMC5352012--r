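test_that("weight normalization gives percent of total absolute weight", {
  expect_equal(normalize_weights(c(2, -1, 1)), c(50, 25, 25))
  expect_equal(normalize_weights(5), 100)
  expect_error(normalize_weights(c(0, 0)), "all weights are zero")
  set.seed(20)
  for (i in 1:25) {
    w <- rnorm(sample(1:12, 1))
    if (all(w == 0)) next
    expect_equal(sum(normalize_weights(w)), 100, tolerance = 1e-9)
  }
})

test_that("bootstrap mean and CI behave on degenerate and large samples", {
  b1 <- bootstrap_mean_ci(rep(3.5, 10), n_boot = 100, seed = 1)
  expect_equal(b1$mean, 3.5)
  expect_equal(b1$ci, c(3.5, 3.5))
  b2 <- bootstrap_mean_ci(7, n_boot = 100, seed = 1)
  expect_equal(b2$mean, 7)
  expect_equal(b2$ci, c(7, 7))
  b3 <- bootstrap_mean_ci(0:99, n_boot = 5000, seed = 2)
  expect_lt(abs(b3$mean - 49.5), 0.5)
  expect_lt(b3$ci[1], 49.5)
  expect_gt(b3$ci[2], 49.5)
  expect_error(bootstrap_mean_ci(numeric(0)), "empty")
  expect_identical(bootstrap_mean_ci(1:30, seed = 9)$ci,
                   bootstrap_mean_ci(1:30, seed = 9)$ci)
})

test_that("key-predictor detection flags the shared structure, not absences", {
  # 8 subjects sharing three predictors with heterogeneous weights, against
  # 19 candidate ROIs
  models <- lapply(1:8, function(s) {
    set.seed(s)
    new_roi_model(0L, c(3L, 7L, 12L), c(0.5, 0.3, 0.15) + rnorm(3, 0, 0.02))
  })
  kp <- identify_key_predictors(models, n_rois = 20, n_perm = 100, seed = 1)
  expect_equal(sort(kp$predictor[kp$key]), c(3L, 7L, 12L))
  absent <- kp[!kp$predictor %in% c(3L, 7L, 12L), ]
  expect_true(all(absent$mean_weight_pct == 0))
  expect_true(all(!absent$key))
  expect_true(all(kp$ci_low <= kp$mean_weight_pct + 1e-9))
  expect_true(all(kp$ci_high >= kp$mean_weight_pct - 1e-9))
  expect_error(identify_key_predictors(models[1], n_rois = 20), "2 subjects")
})

test_that("Bonferroni correction multiplies raw p and caps at 1", {
  models <- lapply(1:6, function(s) {
    set.seed(100 + s)
    new_roi_model(0L, c(2L, 5L), c(0.6, 0.2) + rnorm(2, 0, 0.05))
  })
  k1 <- identify_key_predictors(models, n_rois = 10, n_perm = 100,
                                n_comparisons = 1, seed = 3)
  k9 <- identify_key_predictors(models, n_rois = 10, n_perm = 100,
                                n_comparisons = 9, seed = 3)
  scaled <- pmin(1, k1$p_corrected * 9)
  expect_equal(k9$p_corrected, scaled, tolerance = 1e-12)
  expect_true(all(k9$p_corrected >= k1$p_corrected))
  expect_true(all(k9$p_corrected <= 1))
})

test_that("key-predictor results do not depend on subject order", {
  models <- lapply(1:6, function(s) {
    set.seed(200 + s)
    new_roi_model(0L, c(1L, 4L, 6L), rnorm(3, c(0.5, 0.3, 0.2), 0.05))
  })
  a <- identify_key_predictors(models, n_rois = 12, n_perm = 50, seed = 5)
  b <- identify_key_predictors(rev(models), n_rois = 12, n_perm = 50, seed = 5)
  expect_equal(a, b)
})

test_that("dependencies classify by 50 mm distance, homotopy and hemisphere", {
  parcels <- roinet:::validate_parcels(data.frame(
    label = c("ipc", "ipc", "sfg", "cun"),
    hemisphere = c("left", "right", "left", "left"),
    x_mm = c(-30, 30, -30, -36), y_mm = c(0, 0, 0, 8), z_mm = 0,
    voxel_count = 80L))
  edges <- data.frame(target = c(0L, 0L, 0L), predictor = c(1L, 2L, 3L))
  out <- classify_dependencies(edges, parcels)
  expect_equal(out$kind, c("long", "short", "short"))  # 60, 0, 10 mm
  expect_equal(out$homotopic, c(TRUE, FALSE, FALSE))
  expect_equal(out$interhemispheric, c(TRUE, FALSE, FALSE))
  expect_equal(out$distance_mm, c(60, 0, 10))
  # homotopic edges are always interhemispheric; kinds partition the edges
  expect_true(all(out$interhemispheric[out$homotopic]))
  expect_true(all(out$kind %in% c("short", "long")))
  expect_error(classify_dependencies(data.frame(target = 0L, predictor = 9L),
                                     parcels), "unknown ROI")
})

test_that("weights proportional to activity correlations give r near 1", {
  gt <- make_scenario(n_rois = 16, k_predictors = 4, n_integrators = 3,
                      seed = 7)
  ds <- simulate_dataset(gt, 400, seed = 8)
  sp <- split_segments(400)
  models <- lapply(gt$integrators, function(tg) {
    fit_ols(ds, sp, tg, true_predictors(gt, tg))
  })
  chk <- weight_correlation_check(models, ds, sp, n_shuffle = 500, seed = 1)
  expect_gte(chk$n_pairs, 10L)
  expect_gt(chk$r, 0.5)
  expect_lt(chk$p_value, 0.05)
})

test_that("shuffled weights show no correlation with activity correlations", {
  set.seed(30)
  # hand-built models whose weights ignore the data entirely
  ds <- random_dataset(200, 12, seed = 31)
  models <- lapply(0:3, function(tg) {
    new_roi_model(tg, setdiff(0:11, tg)[1:5], runif(5, 0.1, 1))
  })
  chk <- weight_correlation_check(models, ds, n_shuffle = 500, seed = 2)
  expect_lt(abs(chk$r), 0.5)
  expect_gt(chk$p_value, 0.05)
  one <- list(new_roi_model(0L, 1:5, rep(1, 5)))
  expect_error(weight_correlation_check(one, ds), "at least 10")
})

test_that("partial correlation reduces to plain correlation for an orthogonal covariate", {
  set.seed(40)
  n <- 60
  age <- runif(n, 20, 70)
  measure <- 0.5 * age + rnorm(n, 0, 5)
  motion <- resid(lm(rnorm(n) ~ age + measure))  # orthogonal to both
  pc <- partial_correlation_controlling_motion(measure, age, motion)
  expect_equal(pc$r, cor(measure, age), tolerance = 1e-6)
  expect_lt(pc$p_value, 1e-6)
})

test_that("a fully motion-mediated association has partial correlation near 0", {
  set.seed(41)
  n <- 50
  age <- runif(n, 20, 70)
  motion <- 0.002 * age          # exact function of age
  measure <- 30 * motion         # exact function of motion
  pc <- partial_correlation_controlling_motion(measure, age, motion)
  expect_lt(abs(pc$r), 1e-8)
  expect_error(partial_correlation_controlling_motion(rep(1, n), age, motion),
               "constant")
})
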
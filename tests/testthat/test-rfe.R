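test_that("a 3-ROI trace has exactly two steps with predictor counts 2 and 1", {
  ds <- random_dataset(40, 3, seed = 2)
  tr <- run_rfe(ds, split_segments(40), 0L)
  expect_length(tr$models, 2L)
  expect_equal(tr$n_predictors, c(2L, 1L))
  expect_length(tr$eliminated, 1L)
  expect_length(tr$val_errors, 2L)
  expect_true(all(tr$val_errors >= 0))
  expect_equal(sort(c(tr$eliminated, tr$survivor)), setdiff(0:2, 0L))
})

test_that("each elimination removes exactly the smallest-weight predictor", {
  ds <- random_dataset(60, 6, seed = 3)
  sp <- split_segments(60)
  tr <- run_rfe(ds, sp, 2L)
  for (t in seq_along(tr$eliminated)) {
    m <- tr$models[[t]]
    expect_equal(tr$eliminated[t],
                 m$predictors[which.min(abs(m$std_weights))])
    expect_equal(sort(tr$models[[t + 1]]$predictors),
                 sort(setdiff(m$predictors, tr$eliminated[t])))
  }
})

test_that("an irrelevant predictor is eliminated first", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    T <- 400  # 200 training rows
    x1 <- rnorm(T); x2 <- rnorm(T); x3 <- rnorm(T)
    y <- x1 + x2 + 0.1 * rnorm(T)
    ds <- toy_dataset(cbind(x1, x2, x3, y))
    tr <- run_rfe(ds, split_segments(T), 3L)
    if (tr$eliminated[1] == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("tied smallest weights eliminate the lowest ROI id", {
  set.seed(4)
  T <- 40
  z <- rnorm(T); x2 <- rnorm(T)
  y <- z + x2 + 0.05 * rnorm(T)
  ds <- toy_dataset(cbind(z, z, x2, y))  # duplicated columns share the weight
  tr <- run_rfe(ds, split_segments(T), 3L)
  expect_equal(tr$eliminated[1], 0L)
})

test_that("the suffix-minimum rule keeps exactly the hand-traced predictors", {
  ds <- random_dataset(40, 6, seed = 9)
  sp <- split_segments(40)

  tr <- fake_trace(c(30, 20, 26, 22, 28), target = 5L)
  m <- select_final_rfe(tr, ds, sp)
  expect_equal(sort(m$predictors), sort(c(tr$eliminated[c(2, 4)], tr$survivor)))
  expect_length(m$predictors, 3L)

  tr_dec <- fake_trace(c(50, 40, 30, 20, 10), target = 5L)
  m_dec <- select_final_rfe(tr_dec, ds, sp)
  expect_equal(m_dec$predictors, tr_dec$survivor)

  tr_inc <- fake_trace(c(10, 20, 30, 40, 50), target = 5L)
  m_inc <- select_final_rfe(tr_inc, ds, sp)
  expect_equal(sort(m_inc$predictors),
               sort(c(tr_inc$eliminated, tr_inc$survivor)))
})

test_that("equal validation errors drop the eliminated predictor (strict rule)", {
  tr <- fake_trace(c(20, 20, 25), target = 3L)
  # step 1's elimination left the suffix minimum at 20: not kept
  expect_equal(roinet:::kept_steps(tr), 2L)
})

test_that("RFE2 returns the stored model at the validation-curve minimum", {
  tr <- fake_trace(c(30, 25, 20, 26, 28), target = 5L)
  m <- select_final_rfe2(tr)
  expect_equal(sort(m$predictors), sort(tr$models[[3]]$predictors))
  expect_length(m$predictors, 3L)

  # tie at the minimum: the later step (fewer predictors) wins
  tr_tie <- fake_trace(c(30, 20, 25, 20, 28), target = 5L)
  expect_length(select_final_rfe2(tr_tie)$predictors, 2L)

  # monotonically increasing curve: full model at step one
  tr_inc <- fake_trace(c(10, 20, 30, 40), target = 4L)
  expect_length(select_final_rfe2(tr_inc)$predictors, 4L)
})

test_that("the RFE predictor set is nested in the RFE2 set on random traces", {
  set.seed(123)
  for (rep in 1:100) {
    K <- sample(3:40, 1)
    tr <- fake_trace(runif(K, 10, 100), target = 99L)
    rfe_set <- sort(unique(c(tr$eliminated[roinet:::kept_steps(tr)],
                             tr$survivor)))
    rfe2_set <- sort(select_final_rfe2(tr)$predictors)
    expect_true(all(rfe_set %in% rfe2_set))
    # RFE2 attains the best validation error of any model in the trace
    i2 <- length(tr$val_errors) - length(rfe2_set) + 1L
    expect_equal(tr$val_errors[i2], min(tr$val_errors))
  }
})

test_that("simple regression uses every candidate and matches RFE step one", {
  ds <- random_dataset(60, 7, seed = 10)
  sp <- split_segments(60)
  m <- fit_simple_regression(ds, sp, 4L)
  expect_length(m$predictors, 6L)
  tr <- run_rfe(ds, sp, 4L)
  expect_equal(m$weights, tr$models[[1]]$weights)
  expect_equal(m$validation_error, tr$val_errors[1])
})

test_that("feature selection beats the unselected fit on held-out data", {
  # on sparse ground truth, full-model OLS overfits: its test error should
  # exceed the RFE model's in most replicates
  wins <- 0L
  for (seed in 1:20) {
    gt <- make_scenario(seed = 1)
    ds <- simulate_dataset(gt, 660, seed = seed)
    sp <- split_segments(660)
    tg <- gt$integrators[1]
    obs <- ds$activity[segment_rows(sp, "test"), tg + 1]
    tr <- run_rfe(ds, sp, tg)
    err_rfe <- prediction_error(obs, predict(select_final_rfe(tr, ds, sp),
                                             ds, sp, "test"))
    err_simple <- prediction_error(obs, predict(tr$models[[1]], ds, sp, "test"))
    if (err_simple >= err_rfe) wins <- wins + 1L
  }
  expect_gte(wins, 16L)
})

test_that("fit_roi_model dispatches methods and attaches traces on request", {
  gt <- make_scenario(n_rois = 12, k_predictors = 3, n_integrators = 2,
                      seed = 5)
  ds <- simulate_dataset(gt, 200, seed = 6)
  tg <- gt$integrators[1]
  m <- fit_roi_model(ds, tg, "rfe", keep_trace = TRUE)
  expect_s3_class(m$trace, "rfe_trace")
  expect_equal(m$method, "rfe")
  m2 <- fit_roi_model(ds, tg, "single")
  expect_length(m2$predictors, 1L)
  expect_error(fit_roi_model(ds, tg, "boost"), "arg")
})
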
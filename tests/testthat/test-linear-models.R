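test_that("OLS recovers exact linear dependence with zero training residual", {
  set.seed(7)
  x <- matrix(rnorm(60), 20, 3)
  y <- 2 * x[, 1] - x[, 2]
  ds <- toy_dataset(cbind(x, y))
  sp <- split_segments(20)
  m <- fit_ols(ds, sp, target = 3L, predictors = c(0L, 1L))
  expect_equal(unname(m$weights), c(2, -1), tolerance = 1e-10)
  expect_lt(sum(residuals(m, ds, sp, "train")^2), 1e-18)
})

test_that("an orthogonal predictor gets weight zero", {
  set.seed(8)
  T <- 40
  sp <- split_segments(T)
  tr <- segment_rows(sp, "train")
  x1 <- rnorm(T)
  y <- rnorm(T)
  # orthogonalize on the training segment after centering (the fit's frame)
  xc <- x1; xc[tr] <- resid(lm(x1[tr] ~ y[tr]))
  ds <- toy_dataset(cbind(xc, y))
  m <- fit_ols(ds, sp, target = 1L, predictors = 0L)
  expect_lt(abs(m$weights), 1e-10)
})

test_that("OLS matches the normal-equations oracle on random instances", {
  for (seed in 1:5) {
    ds <- random_dataset(100, 6, seed = seed)  # 50 training rows, 5 predictors
    sp <- split_segments(100)
    m <- fit_ols(ds, sp, target = 5L, predictors = 0:4)
    expect_equal(unname(m$weights), unname(ols_oracle(ds, sp, 5L, 0:4)),
                 tolerance = 1e-8)
  }
})

test_that("training residuals are orthogonal to every included predictor", {
  ds <- random_dataset(80, 8, seed = 3)
  sp <- split_segments(80)
  m <- fit_ols(ds, sp, target = 0L, predictors = 1:7)
  r <- residuals(m, ds, sp, "train")
  tr <- segment_rows(sp, "train")
  for (j in m$predictors) {
    expect_lt(abs(sum(r * ds$activity[tr, j + 1])), 1e-8)
  }
})

test_that("underdetermined OLS warns and returns the minimum-norm solution", {
  ds <- random_dataset(16, 12, seed = 5)  # 8 training rows, 11 predictors
  sp <- split_segments(16)
  expect_warning(m <- fit_ols(ds, sp, target = 0L, predictors = 1:11),
                 "minimum-norm")
  expect_lt(sum(residuals(m, ds, sp, "train")^2), 1e-16)
})

test_that("OLS rejects bad predictor lists", {
  ds <- random_dataset(20, 4)
  sp <- split_segments(20)
  expect_error(fit_ols(ds, sp, 0L, integer(0)), "empty predictor")
  expect_error(fit_ols(ds, sp, 0L, c(0L, 1L)), "own predictor")
})

test_that("single-best-predictor selection uses training-segment correlation", {
  # a copy of the target is found with weight 1
  set.seed(11)
  x <- matrix(rnorm(120), 40, 3)
  ds <- toy_dataset(cbind(x, x[, 3]))
  sp <- split_segments(40)
  m <- fit_single_best_predictor(ds, sp, 3L)
  expect_equal(m$predictors, 2L)
  expect_equal(unname(m$weights), 1, tolerance = 1e-10)
  expect_equal(m$fit_method, "single_predictor")

  # training-best beats validation-best: x0 tracks the target only on the
  # training rows, x1 only on the validation rows
  set.seed(12)
  T <- 40
  sp <- split_segments(T)
  y <- rnorm(T)
  x0 <- rnorm(T); x1 <- rnorm(T)
  x0[segment_rows(sp, "train")] <- y[segment_rows(sp, "train")]
  x1[segment_rows(sp, "validation")] <- y[segment_rows(sp, "validation")]
  ds <- toy_dataset(cbind(x0, x1, y))
  m <- fit_single_best_predictor(ds, sp, 2L)
  expect_equal(m$predictors, 0L)
})

test_that("exact correlation ties break toward the lowest ROI id", {
  set.seed(13)
  x <- rnorm(30)
  y <- x + 0.1 * rnorm(30)
  ds <- toy_dataset(cbind(x, -x, y))  # |cor| identical for ROIs 0 and 1
  m <- fit_single_best_predictor(ds, split_segments(30), 2L)
  expect_equal(m$predictors, 0L)
})

test_that("lasso path starts all-zero at c_max and reaches OLS as c -> 0", {
  ds <- random_dataset(80, 6, seed = 21)
  sp <- split_segments(80)
  path <- roinet:::penalized_path(ds, sp, 5L, 0:4, mix = 1, n_c = 200,
                                  lambda_min_ratio = 1e-6)
  expect_true(all(path$weights[, 1] == 0))
  w_ols <- fit_ols(ds, sp, 5L, 0:4)$std_weights
  expect_equal(unname(path$weights[, ncol(path$weights)]), unname(w_ols),
               tolerance = 1e-4)
})

test_that("every lasso path solution satisfies the KKT subgradient conditions", {
  for (seed in 1:4) {
    ds <- random_dataset(60, 5, seed = 100 + seed)  # 30 training rows, 4 predictors
    sp <- split_segments(60)
    path <- roinet:::penalized_path(ds, sp, 4L, 0:3, mix = 1, n_c = 60,
                                    lambda_min_ratio = 1e-4)
    sys <- standardized_system(ds, sp, 4L, 0:3)
    viol <- vapply(seq_along(path$c_grid), function(i) {
      kkt_violation(sys$x, sys$y, path$weights[, i], path$c_grid[i], mix = 1)
    }, numeric(1))
    expect_lt(max(viol), 1e-6)
  }
})

test_that("the selected lasso model minimizes validation error over its grid", {
  ds <- random_dataset(120, 8, seed = 31)
  sp <- split_segments(120)
  m <- fit_lasso_path(ds, sp, 0L)
  path <- roinet:::penalized_path(ds, sp, 0L, 1:7, mix = 1, n_c = 200,
                                  lambda_min_ratio = 1e-4)
  expect_lte(m$validation_error, min(path$val_errors) + 1e-9)
  expect_true(all(m$weights != 0))  # zero-weight predictors dropped
})

test_that("active-set size is essentially monotone along the lasso path", {
  # the number of nonzero weights grows as c shrinks; brief unit dips can
  # occur near degeneracies, so small transient violations are tolerated
  ds <- random_dataset(100, 10, seed = 41)
  sp <- split_segments(100)
  path <- roinet:::penalized_path(ds, sp, 0L, 1:9, mix = 1, n_c = 100,
                                  lambda_min_ratio = 1e-4)
  nz <- unname(colSums(path$weights != 0))
  dips <- diff(nz)[diff(nz) < 0]
  expect_lte(length(dips), 5)
  expect_equal(nz[1], 0)
  expect_equal(nz[length(nz)], max(nz))
})

test_that("elastic net at mix 1 reproduces the lasso path", {
  ds <- random_dataset(80, 6, seed = 51)
  sp <- split_segments(80)
  p1 <- roinet:::penalized_path(ds, sp, 0L, 1:5, mix = 1, n_c = 50,
                                lambda_min_ratio = 1e-4)
  m_en <- fit_elastic_net_grid(ds, sp, 0L, fit_config(enet_mixes = 1,
                                                      n_enet_lambdas = 50))
  m_la <- fit_lasso_path(ds, sp, 0L, fit_config(n_lasso_lambdas = 50))
  expect_equal(m_en$predictors, m_la$predictors)
  expect_equal(m_en$weights, m_la$weights, tolerance = 1e-8)
})

test_that("elastic net spreads weight over duplicated predictors, lasso picks one", {
  set.seed(61)
  T <- 80
  z <- rnorm(T)
  x3 <- rnorm(T); x4 <- rnorm(T)
  y <- z + 0.3 * x3 + 0.1 * rnorm(T)
  ds <- toy_dataset(cbind(z, z, x3, x4, y))  # ROIs 0 and 1 duplicated
  sp <- split_segments(T)
  getw <- function(m, id) {
    if (id %in% m$predictors) m$weights[match(id, m$predictors)] else 0
  }
  en <- fit_elastic_net_grid(ds, sp, 4L,
                             fit_config(enet_mixes = 0.05, n_enet_lambdas = 50))
  expect_equal(getw(en, 0L), getw(en, 1L), tolerance = 1e-6)
  expect_gt(abs(getw(en, 0L)), 0.01)
  la <- fit_lasso_path(ds, sp, 4L, fit_config(n_lasso_lambdas = 50))
  w_la <- abs(c(getw(la, 0L), getw(la, 1L)))
  expect_gt(max(w_la) - min(w_la), 0.1 * max(w_la))
})

test_that("predict is the plain weighted sum of predictor activities", {
  act <- cbind(c(1, 0, 2, 1, -1, 0, 1, 2), c(0, 1, 1, 0, 2, 1, 0, -1),
               rnorm(8))
  ds <- toy_dataset(act)
  sp <- split_segments(8)
  m0 <- new_roi_model(2L, c(0L, 1L), c(0, 0))
  expect_equal(predict(m0, ds, sp, "all"), rep(0, 8))
  m1 <- new_roi_model(2L, 0L, 1)
  expect_equal(predict(m1, ds, sp, "all"), ds$activity[, 1])
  m2 <- new_roi_model(2L, c(0L, 1L), c(2, -1))
  expect_equal(predict(m2, ds, sp, "all"),
               2 * ds$activity[, 1] - ds$activity[, 2])
  bad <- new_roi_model(2L, 7L, 1)
  expect_error(predict(bad, ds, sp), "absent from dataset")
})
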
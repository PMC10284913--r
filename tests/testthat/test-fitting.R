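test_that("spline resampling interpolates measurements exactly", {
  # linear data stay linear
  tt <- c(0, 2, 5, 7, 10)
  tr <- spline_resample(tt, 3 + 2 * tt, step = 0.5)
  expect_equal(tr$volume, 3 + 2 * tr$time, tolerance = 1e-10)
  # quadratic data reproduced at the knots
  tr <- spline_resample(tt, tt^2, step = 0.5)
  at_knots <- tr$volume[tr$time %in% tt]
  expect_equal(at_knots, tt^2, tolerance = 1e-10)
  # sparse exponential measurements recovered to 1e-3 between knots
  tt <- c(0, 3, 5, 8, 10)
  tr <- spline_resample(tt, exp(0.109 * tt), step = 0.1)
  expect_lt(max(abs(tr$volume - exp(0.109 * tr$time))), 1e-3)
  expect_error(spline_resample(c(0, 1, 2), c(1, 2, 3)), "4")
  expect_error(spline_resample(c(0, 2, 1, 3), 1:4), "increasing")
})

test_that("MSE matches hand arithmetic and its invariances", {
  expect_identical(mse(c(1, 2), c(1, 2)), 0)
  expect_equal(mse(c(1, 2), c(0, 0)), 2.5)
  set.seed(42)
  y <- runif(100)
  expect_equal(mse(y + 0.1, y), 0.01)
  # permutation of paired samples leaves MSE unchanged
  yhat <- y + rnorm(100, sd = 0.3)
  p <- sample(100)
  expect_equal(mse(y, yhat), mse(y[p], yhat[p]))
  # quadratic under common scaling
  expect_equal(mse(3 * y, 3 * yhat), 9 * mse(y, yhat))
  # misaligned grids are an error
  expect_error(mse(trajectory(0:3, 1:4), trajectory(1:4, 1:4)), "grids")
  expect_error(mse(1:3, 1:4), "length")
})

test_that("integer stage recovers generating parameters from noiseless data", {
  # exponential, far start
  data <- dense_fixture(growth_model("exponential", a = 0.109), v0 = 0.5)
  fit <- fit_integer("exponential", data, init = c(a = 0.05))
  expect_equal(fit$model$params$a, 0.109, tolerance = 1e-3)
  expect_lt(fit$mse, 1e-8)
  expect_true(fit$converged)

  # logistic, started at the optimum: immediate near-zero MSE
  m <- growth_model("logistic", a = 0.0735, k = 2.81, b = 3.35)
  data <- dense_fixture(m, v0 = 1)
  fit <- fit_integer("logistic", data, init = c(a = 0.0735, k = 2.81,
                                                b = 3.35))
  expect_lt(fit$mse, 1e-8)

  # gompertz from a 0.5x start
  m <- growth_model("gompertz", a = 0.106, b = 26.09, c = 2.24)
  data <- dense_fixture(m, v0 = 0.25)
  fit <- fit_integer("gompertz", data,
                     init = c(a = 0.053, b = 13.05, c = 1.12))
  expect_lt(fit$mse, 1e-6)
})

test_that("alpha stage recovers the generating fractional order", {
  m <- growth_model("gompertz", a = 0.106, b = 26.09, c = 2.24)
  data <- dense_fixture(m, alpha = 0.86, v0 = 0.25)
  fa <- fit_alpha(m, data)
  sweep <- fa$sweep
  expect_equal(fa$fit$alpha, 0.86, tolerance = 0.011)
  expect_lt(fa$fit$mse, 1e-6)
  # interior minimum: strictly worse away from the optimum (Fig.-style dip)
  m080 <- sweep$mse[abs(sweep$alpha - 0.80) < 1e-9]
  m095 <- sweep$mse[abs(sweep$alpha - 0.95) < 1e-9]
  expect_gt(m080, fa$fit$mse)
  expect_gt(m095, fa$fit$mse)
  # unimodal on the grid: the discrete differences change sign once
  signs <- sign(diff(sweep$mse))
  expect_lte(sum(diff(signs[signs != 0]) != 0), 1)

  # data generated at integer order put the optimum on the boundary
  data1 <- dense_fixture(m, alpha = 1, v0 = 0.25)
  fa1 <- fit_alpha(m, data1)
  expect_equal(fa1$fit$alpha, 1)
  expect_error(fit_alpha(m, data1, alpha_grid = seq(0.7, 0.9, 0.01)),
               "1.0")
})

test_that("two-stage fit never loses to the integer stage and ties break low", {
  ex <- simulate_experiment(growth_model("exponential", a = 0.109),
                            alpha = 0.9, v0_mm3 = 50, sigma = 0.02,
                            seed = 11)
  fit <- fracfit(as_model_units(ex), kind = "exponential")
  expect_lte(fit$fractional$mse, fit$integer$mse)
  expect_equal(fit$sweep$mse[fit$sweep$alpha == 1], fit$integer$mse,
               tolerance = 1e-12)
  expect_equal(attr(fit$sweep, "argmin_alpha"), fit$fractional$alpha)
  # methods are coherent
  expect_named(coef(fit), c("a", "alpha"))
  expect_equal(length(residuals(fit)), nrow(fit$resampled))
  pr <- predict(fit, order = "integer")
  expect_s3_class(pr, "trajectory")
  sims <- simulate(fit, nsim = 3, seed = 1, sigma = 0.05)
  expect_equal(dim(sims), c(nrow(ex$measurements), 4L))
})

test_that("comparison report computes MSE ratios and isolates failures", {
  # ratio arithmetic on published error pairs
  expect_equal(mse_reduction_percent(0.8557, 0.2243), 26.21,
               tolerance = 1e-4)
  expect_equal(mse_reduction_percent(0.5, 0.5), 100)

  m <- growth_model("exponential", a = 0.109)
  sets <- list(
    treated = as_model_units(simulate_experiment(
      m, alpha = 0.9, v0_mm3 = 80, protocol = treatment_protocol(),
      sigma = 0.02, seed = 5)),
    untreated = as_model_units(simulate_experiment(
      m, alpha = 0.9, v0_mm3 = 50, sigma = 0.02, seed = 6)))
  rep <- compare_models(sets, kinds = c("exponential", "gompertz"),
                        control = list(maxit = 400L, restarts = 0L))
  expect_s3_class(rep, "growth_comparison")
  expect_equal(nrow(rep), 4L)
  ok <- !is.na(rep$integer_mse)
  expect_true(all(rep$fractional_mse[ok] <= rep$integer_mse[ok]))
  expect_equal(rep$ratio_percent[ok],
               100 * rep$fractional_mse[ok] / rep$integer_mse[ok])

  # a dataset whose first volume is zero breaks the ln(v) law only;
  # the report still carries the other fits
  zero_start <- trajectory(seq(0, 18, by = 2), c(0, 1:9))
  rep2 <- compare_models(list(d = zero_start),
                         kinds = c("bp_particular", "exponential"),
                         control = list(maxit = 200L, restarts = 0L))
  expect_true(any(!is.na(rep2$error)))
  expect_true(any(is.na(rep2$error)))
})
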
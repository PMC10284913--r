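fast_exp <- function(a = 0.3) growth_model("exponential", a = a)

test_that("dosing follows the protocol: trigger threshold and refractory gap", {
  # fast-growing treated tumor: crosses 200 mm^3 early, doses spaced >= 10 d
  ex <- simulate_experiment(fast_exp(), alpha = 1, v0_mm3 = 120,
                            protocol = treatment_protocol(),
                            kill_fraction = 0.4, sigma = 0.02, seed = 2,
                            solver_step = 0.05)
  expect_gt(length(ex$doses), 0)
  meas <- ex$measurements
  for (d in ex$doses)
    expect_gte(meas$volume_mm3[meas$time_days == d], 200)
  if (length(ex$doses) > 1)
    expect_true(all(diff(ex$doses) >= 10))
  # the first sample at or above threshold is a dose time
  first_cross <- meas$time_days[which(meas$volume_mm3 >= 200)[1]]
  expect_equal(ex$doses[1], first_cross)
})

test_that("censoring stops the experiment at the first sample over 2000 mm^3", {
  ex <- simulate_experiment(fast_exp(0.35), alpha = 1, v0_mm3 = 400,
                            sigma = 0.02, seed = 3, solver_step = 0.05)
  v <- ex$measurements$volume_mm3
  expect_gte(v[length(v)], 2000)
  expect_true(all(v[-length(v)] < 2000))
})

test_that("generation is seed-reproducible and kappa = 0 matches untreated", {
  m <- growth_model("exponential", a = 0.109)
  a1 <- simulate_experiment(m, alpha = 0.9, v0_mm3 = 80,
                            protocol = treatment_protocol(),
                            sigma = 0.05, seed = 7, solver_step = 0.05)
  a2 <- simulate_experiment(m, alpha = 0.9, v0_mm3 = 80,
                            protocol = treatment_protocol(),
                            sigma = 0.05, seed = 7, solver_step = 0.05)
  expect_identical(a1$measurements, a2$measurements)
  expect_identical(a1$doses, a2$doses)
  # kappa = 0: doses are logged but the trajectory is the untreated one
  tr0 <- simulate_experiment(m, alpha = 0.9, v0_mm3 = 80,
                             protocol = treatment_protocol(),
                             kill_fraction = 0, sigma = 0.05, seed = 7,
                             solver_step = 0.05)
  un <- simulate_experiment(m, alpha = 0.9, v0_mm3 = 80, sigma = 0.05,
                            seed = 7, solver_step = 0.05)
  expect_equal(tr0$measurements, un$measurements)
  expect_gt(length(tr0$doses), 0)
})

test_that("noise-free samples sit on the solved trajectory; noise has median one", {
  m <- growth_model("gompertz", a = 0.106, b = 26.09, c = 2.24)
  ex <- simulate_experiment(m, alpha = 0.86, v0_mm3 = 50, sigma = 0,
                            seed = 1, solver_step = 0.05)
  on_grid <- ex$trajectory$volume[match(ex$measurements$time_days,
                                        ex$trajectory$time)]
  expect_equal(ex$measurements$volume_mm3, on_grid, tolerance = 1e-12)

  # ratio of noisy to noise-free measurements averages ~1 over 1000 draws
  mfast <- growth_model("exponential", a = 0.109)
  base <- simulate_experiment(mfast, v0_mm3 = 50, sigma = 0, seed = 1,
                              solver_step = 0.25)
  ratios <- unlist(lapply(1:125, function(s) {
    noisy <- simulate_experiment(mfast, v0_mm3 = 50, sigma = 0.05,
                                 seed = s, solver_step = 0.25)
    noisy$measurements$volume_mm3 / base$measurements$volume_mm3
  }))
  expect_equal(length(ratios), 1000L)
  expect_equal(mean(ratios), 1, tolerance = 0.01)
})

test_that("fixture pairs are byte-stable and round-trip through CSV", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- make_fixture_pair(d1, seed = 1, solver_step = 0.05)
  fx2 <- make_fixture_pair(d2, seed = 1, solver_step = 0.05)
  for (f in c("treated.csv", "untreated.csv", "manifest.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # 18-day horizon at 2-3 day cadence: 7-10 measurement rows
  un <- read_trajectory_csv(file.path(d1, "untreated.csv"))
  expect_gte(nrow(un), 7)
  expect_lte(nrow(un), 10)
  expect_equal(un$volume_mm3,
               fx1$untreated$measurements$volume_mm3, tolerance = 1e-12)
  # manifest carries the generating truth
  man <- jsonlite::read_json(file.path(d1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$model, "exponential")
  expect_equal(man$alpha, 0.98)
})

test_that("noiseless integer fixtures round-trip through the fitter", {
  d <- withr::local_tempdir()
  fx <- make_fixture_pair(d, seed = 4, alpha = 1, sigma = 0,
                          solver_step = 0.02)
  data <- as_model_units(read_trajectory_csv(file.path(d, "untreated.csv")))
  fit <- fracfit(data, kind = "exponential")
  expect_equal(fit$integer$model$params$a, fx$manifest$params$a,
               tolerance = 0.01)
})
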
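test_that("growth rates match direct arithmetic at published parameter values", {
  # exponential: linear in v
  m <- growth_model("exponential", a = 0.046)
  expect_equal(growth_rate(m, 1), 0.046)
  expect_equal(growth_rate(growth_model("exponential", a = 0.109), c(0, 2)),
               c(0, 0.218))

  # logistic: equilibria at 0 and k, direct value at v = 1
  m <- growth_model("logistic", a = 0.0735, k = 2.81, b = 3.35)
  expect_equal(growth_rate(m, c(0, 2.81)), c(0, 0))
  expect_equal(growth_rate(m, 1), 0.0735 * (1 - (1 / 2.81)^3.35))

  # gompertz: zero where v + c = b, both published forms
  for (form in c("with_v", "without_v")) {
    m <- growth_model("gompertz", a = 0.106, b = 26.09, c = 2.24,
                      gompertz_form = form)
    expect_equal(growth_rate(m, 26.09 - 2.24), 0)
  }
  m <- growth_model("gompertz", a = 0.106, b = 26.09, c = 2.24)
  expect_equal(growth_rate(m, 1), 0.106 * 1 * log(26.09 / (1 + 2.24)))
  m <- growth_model("gompertz", a = 0.204, b = 8.81, c = 5.04,
                    gompertz_form = "without_v")
  expect_equal(growth_rate(m, 0), 0.204 * log(8.81 / 5.04))

  # Bertalanffy-Putter: v = 1 collapses the power terms
  m <- growth_model("bp_general", p = 0.168, q = 0.1, a = 2.18, b = 2.66)
  expect_equal(growth_rate(m, 1), 0.168 - 0.1)
  m <- growth_model("bp_general", p = 0.894, q = 0.741, a = 1.38, b = 1.44)
  expect_equal(growth_rate(m, 2), 0.894 * 2^1.38 - 0.741 * 2^1.44)
  m <- growth_model("bp_particular", p = 0.064, q = 0.063, a = 2.41)
  expect_equal(growth_rate(m, 1), 0.064)
  # power-balance equilibrium of the general form: p v^a = q v^b
  m <- growth_model("bp_general", p = 0.168, q = 0.1, a = 2.18, b = 2.66)
  veq <- (0.168 / 0.1)^(1 / (2.66 - 2.18))
  expect_equal(growth_rate(m, veq), 0, tolerance = 1e-12)
})

test_that("parameter validation enforces the laws' constraints", {
  expect_error(growth_model("exponential", a = -1), "positive")
  expect_error(growth_model("logistic", a = 0.1, k = 2), "parameters")
  expect_error(growth_model("bp_general", p = 1, q = 1, a = 2, b = 2),
               "a != b")
  # the logistic k must reach `...`, not partially match the first formal
  m <- growth_model("logistic", a = 0.565, k = 35.2, b = 0.134)
  expect_equal(m$params$k, 35.2)
  expect_error(growth_rate(growth_model("exponential", a = 1), -1), "v >= 0")
  expect_error(growth_rate(growth_model("bp_particular",
                                        p = 0.2, q = 0.01, a = 0.74), 0),
               "v > 0")
})

test_that("rates are finite and sign-correct below carrying capacity", {
  sets <- fitted_models()
  for (arm in sets) {
    for (entry in arm) {
      v <- seq(0.01, 1, length.out = 50)
      r <- growth_rate(entry$model, v)
      expect_true(all(is.finite(r)))
      if (entry$model$kind %in% c("logistic", "gompertz"))
        expect_true(all(r > 0))  # well below k and b - c
    }
  }
})

test_that("fractional exponential closed form behaves like its limits", {
  expect_equal(ml_exponential(0, a = 0.109, alpha = 0.98, v0 = 3), 3)
  expect_equal(ml_exponential(10, a = 0.046, alpha = 1, v0 = 1), exp(0.46))
  v <- ml_exponential(seq(0, 18, by = 1), a = 0.109, alpha = 0.98)
  expect_true(all(diff(v) > 0))
})

test_that("integer-order closed forms agree with an adaptive ODE reference", {
  skip_if_not_installed("deSolve")
  times <- seq(0, 18, by = 0.5)
  expo <- growth_model("exponential", a = 0.109)
  expect_equal(analytic_integer_solution(expo, 0.5, times)$volume,
               0.5 * exp(0.109 * times))
  expect_equal(analytic_integer_solution(expo, 0.5, 18)$volume,
               0.5 * exp(1.962))
  logi <- growth_model("logistic", a = 0.565, k = 35.2, b = 0.134)
  expect_equal(analytic_integer_solution(logi, 0.5, times)$volume,
               desolve_reference(logi, 0.5, times), tolerance = 1e-8)
  # starting at carrying capacity stays there
  expect_equal(analytic_integer_solution(logi, 35.2, times)$volume,
               rep(35.2, length(times)))
  expect_error(analytic_integer_solution(
    growth_model("gompertz", a = 1, b = 2, c = 1), 0.5, times),
    "closed form")
})

test_that("trajectories from positive starts stay non-negative at fitted scales", {
  sets <- fitted_models()
  for (arm in sets) {
    for (entry in arm) {
      tr <- solve_caputo_ivp(entry$model, alpha = entry$alpha, v0 = 0.01,
                             times = seq(0, 18, by = 0.05), nonneg = TRUE)
      expect_true(all(tr$volume >= 0))
    }
  }
})
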
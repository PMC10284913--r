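# Published fitted parameter sets for the five growth laws, per study arm,
# with the corresponding fitted fractional orders. Used as realistic
# parameter scales throughout the suite.
fitted_models <- function() {
  list(
    treated = list(
      exponential   = list(model = growth_model("exponential", a = 0.046),
                           alpha = 0.97),
      logistic      = list(model = growth_model("logistic", a = 0.0735,
                                                k = 2.81, b = 3.35),
                           alpha = 0.94),
      gompertz      = list(model = growth_model("gompertz", a = 0.204,
                                                b = 8.81, c = 5.04,
                                                gompertz_form = "without_v"),
                           alpha = 0.95),
      bp_general    = list(model = growth_model("bp_general", p = 0.168,
                                                q = 0.1, a = 2.18, b = 2.66),
                           alpha = 0.96),
      bp_particular = list(model = growth_model("bp_particular", p = 0.064,
                                                q = 0.063, a = 2.41),
                           alpha = 0.96)),
    untreated = list(
      exponential   = list(model = growth_model("exponential", a = 0.109),
                           alpha = 0.98),
      logistic      = list(model = growth_model("logistic", a = 0.565,
                                                k = 35.2, b = 0.134),
                           alpha = 0.88),
      gompertz      = list(model = growth_model("gompertz", a = 0.106,
                                                b = 26.09, c = 2.24,
                                                gompertz_form = "without_v"),
                           alpha = 0.86),
      bp_general    = list(model = growth_model("bp_general", p = 0.894,
                                                q = 0.741, a = 1.38,
                                                b = 1.44),
                           alpha = 0.96),
      bp_particular = list(model = growth_model("bp_particular", p = 0.203,
                                                q = 0.011, a = 0.74),
                           alpha = 0.95)))
}

# noiseless dense trajectory of `model` at order `alpha` on the fitting grid
dense_fixture <- function(model, alpha = 1, v0 = 0.25, step = 0.1,
                          horizon = 18) {
  solve_caputo_ivp(model, alpha = alpha, v0 = v0,
                   times = seq(0, horizon, by = step), nonneg = TRUE)
}

# classical adaptive ODE reference (independent of the package solver)
desolve_reference <- function(model, v0, times, rtol = 1e-10) {
  out <- deSolve::lsoda(
    y = c(v = v0), times = times,
    func = function(t, y, parms) list(growth_rate(model, max(y, 0))),
    rtol = rtol, atol = rtol)
  as.numeric(out[, "v"])
}
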
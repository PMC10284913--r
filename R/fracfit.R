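#' Two-stage fractional growth-model fit
#'
#' The package's main fitting entry point. Given sparse tumor-volume
#' measurements it (1) resamples them onto a uniform grid with a cubic
#' spline, (2) estimates the growth law's kinetic parameters at integer
#' order (\eqn{\alpha = 1}) by Nelder-Mead minimization of the MSE, and
#' (3) freezes those parameters and searches a one-dimensional grid for the
#' Caputo fractional order \eqn{\alpha} that minimizes the MSE of the
#' fractional trajectory. The extra degree of freedom \eqn{\alpha} encodes
#' the memory of the growth process; \eqn{\alpha = 1} recovers the
#' classical model exactly.
#'
#' The initial volume is fixed to the first resampled observation, so the
#' kinetic parameters are not confounded with the initial condition.
#'
#' @param data measurements: a [trajectory()], a data.frame with columns
#'   \code{time}/\code{volume} (or \code{time_days}/\code{volume_mm3}, which
#'   are converted by \code{unit_factor}), in model volume units unless the
#'   mm^3 columns are used.
#' @param kind growth-law kind, see [growth_model()].
#' @param init optional named starting parameters; defaults to crude
#'   data-driven heuristics.
#' @param alpha_grid grid of candidate fractional orders in (0, 1],
#'   containing 1.0; default \code{seq(0.7, 1, 0.01)}.
#' @param grid_step resampling step in days (default 0.1).
#' @param gompertz_form Gompertz variant, see [growth_model()].
#' @param unit_factor mm^3 per model volume unit (default 100), applied only
#'   when the data carry a \code{volume_mm3} column.
#' @param control optimizer settings, see [fit_integer()].
#' @return an object of class \code{"fracfit"} with components
#'   \code{kind}, \code{integer} and \code{fractional} (both
#'   \code{"fit_result"}), \code{sweep} (the MSE-alpha curve),
#'   \code{data} (measurements used) and \code{resampled} (the fitting
#'   grid). Supports \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{fitted}, \code{residuals}, \code{plot} and
#'   \code{simulate}.
#' @examples
#' \donttest{
#' tr <- simulate_experiment(growth_model("exponential", a = 0.109),
#'                           alpha = 0.9, v0_mm3 = 50, sigma = 0.02,
#'                           seed = 1)
#' fit <- fracfit(as_model_units(tr$measurements), kind = "exponential")
#' fit
#' }
#' @export
fracfit <- function(data, kind = c("exponential", "logistic", "gompertz",
                                   "bp_general", "bp_particular"),
                    init = NULL,
                    alpha_grid = seq(0.7, 1, by = 0.01),
                    grid_step = 0.1,
                    gompertz_form = c("with_v", "without_v"),
                    unit_factor = 100, control = list()) {
  kind <- match.arg(kind)
  gompertz_form <- match.arg(gompertz_form)
  cl <- match.call()
  if (is.data.frame(data) && all(c("time_days", "volume_mm3") %in% names(data)))
    data <- trajectory(data$time_days, data$volume_mm3 / unit_factor)
  if (!inherits(data, "trajectory"))
    data <- trajectory(data$time, data$volume)
  resampled <- spline_resample(data$time, data$volume, step = grid_step)
  if (is.null(init)) init <- default_init(kind, resampled)
  int_fit <- fit_integer(kind, resampled, init = init,
                         gompertz_form = gompertz_form, control = control)
  fa <- fit_alpha(int_fit$model, resampled, alpha_grid = alpha_grid,
                  v0 = int_fit$v0)
  structure(list(kind = kind, call = cl,
                 integer = int_fit, fractional = fa$fit, sweep = fa$sweep,
                 data = data, resampled = resampled,
                 gompertz_form = gompertz_form),
            class = "fracfit")
}

# crude, data-driven starting values; recovery-grade starts should be
# supplied explicitly via `init`
default_init <- function(kind, tr) {
  v <- pmax(tr$volume, 1e-6)
  span <- tr$time[nrow(tr)] - tr$time[1]
  a0 <- max(log(v[length(v)] / v[1]) / span, 0.01)
  vmax <- max(v)
  switch(kind,
         exponential   = c(a = a0),
         logistic      = c(a = a0, k = 1.2 * vmax, b = 1),
         gompertz      = c(a = a0, b = 1.5 * vmax, c = 0.2 * vmax),
         bp_general    = c(p = a0, q = a0 / 2, a = 1.1, b = 1.5),
         bp_particular = c(p = a0, q = a0 / 2, a = 1.1))
}

#' @export
print.fracfit <- function(x, ...) {
  cat("Two-stage fractional growth-model fit [", x$kind, "]\n", sep = "")
  cat("  integer order (alpha = 1):    MSE =",
      format(x$integer$mse, digits = 6), "\n")
  cat("  fractional order alpha =", format(x$fractional$alpha),
      ":  MSE =", format(x$fractional$mse, digits = 6), "\n")
  cat("  retained MSE:",
      sprintf("%.2f%%", mse_reduction_percent(x$integer$mse,
                                              x$fractional$mse)),
      "of the integer-order error\n")
  cat("  kinetic parameters (Nelder-Mead,", x$integer$n_evaluations,
      "evaluations):\n")
  print(x$integer$model)
  invisible(x)
}

#' @export
coef.fracfit <- function(object, ...) {
  c(unlist(object$integer$model$params), alpha = object$fractional$alpha)
}

#' @export
summary.fracfit <- function(object, ...) {
  wp <- wellposedness_report(
    object$integer$model, alpha = object$fractional$alpha,
    v_range = c(max(min(object$resampled$volume), 1e-3),
                max(object$resampled$volume)),
    t_bound = max(object$resampled$time))
  structure(list(fit = object, wellposedness = wp), class = "summary.fracfit")
}

#' @export
print.summary.fracfit <- function(x, ...) {
  print(x$fit)
  s <- x$fit$sweep
  cat("  MSE-alpha sweep:", nrow(s), "orders in [",
      format(min(s$alpha)), ",", format(max(s$alpha)), "]\n")
  cat("Well-posedness diagnostics:\n")
  print(x$wellposedness)
  invisible(x)
}

#' Predict trajectories from a fitted fractional growth model
#'
#' @param object a [fracfit()] object.
#' @param times uniform time grid (days); defaults to the resampled fitting
#'   grid.
#' @param order \code{"fractional"} (fitted alpha) or \code{"integer"}
#'   (alpha = 1).
#' @param ... unused.
#' @return a [trajectory()].
#' @export
predict.fracfit <- function(object, times = NULL,
                            order = c("fractional", "integer"), ...) {
  order <- match.arg(order)
  if (is.null(times)) times <- object$resampled$time
  fit <- object[[order]]
  solve_on_grid(fit$model, alpha = fit$alpha, v0 = fit$v0, times = times)
}

#' @export
fitted.fracfit <- function(object, order = c("fractional", "integer"), ...) {
  predict(object, order = match.arg(order))$volume
}

#' @export
residuals.fracfit <- function(object, order = c("fractional", "integer"),
                              ...) {
  object$resampled$volume - fitted(object, order = match.arg(order))
}

#' Plot a fractional growth-model fit
#'
#' Two panels: the measurements with the integer- and fractional-order
#' fitted curves, and the MSE-vs-alpha sweep with its arg-min marked.
#'
#' @param x a [fracfit()] object.
#' @param ... passed to the first \code{plot} call.
#' @export
plot.fracfit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  pi_ <- predict(x, order = "integer")
  pf <- predict(x, order = "fractional")
  graphics::plot(x$data$time, x$data$volume, pch = 19,
                 xlab = "time [days]", ylab = "volume [model units]",
                 main = paste0(x$kind, " fit"),
                 ylim = range(x$data$volume, pi_$volume, pf$volume), ...)
  graphics::lines(pi_$time, pi_$volume, col = "blue", lwd = 2)
  graphics::lines(pf$time, pf$volume, col = "red", lwd = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c("data",
                              "integer order",
                              sprintf("fractional (alpha = %.2f)",
                                      x$fractional$alpha)),
                   col = c("black", "blue", "red"),
                   pch = c(19, NA, NA), lty = c(NA, 1, 1), lwd = 2)
  s <- x$sweep[x$sweep$ok, ]
  graphics::plot(s$alpha, s$mse, type = "b", pch = 20,
                 xlab = "fractional order alpha", ylab = "MSE",
                 main = "MSE-alpha sweep")
  graphics::abline(v = x$fractional$alpha, lty = 2, col = "red")
  invisible(x)
}

#' Simulate noisy measurement replicates from a fitted model
#'
#' Draws new measurement sets at the original measurement times from the
#' fitted fractional trajectory under the package's multiplicative
#' lognormal noise model (median 1).
#'
#' @param object a [fracfit()] object.
#' @param nsim number of replicate measurement sets.
#' @param seed integer seed (optional).
#' @param sigma relative noise level (default 0.05).
#' @param ... unused.
#' @return a data.frame with the measurement times and one column per
#'   replicate.
#' @export
simulate.fracfit <- function(object, nsim = 1, seed = NULL, sigma = 0.05,
                             ...) {
  if (!is.null(seed)) set.seed(seed)
  tt <- object$data$time
  dense <- predict(object, order = "fractional")
  base <- stats::approx(dense$time, dense$volume, xout = tt)$y
  out <- data.frame(time = tt)
  for (i in seq_len(nsim))
    out[[paste0("sim_", i)]] <-
      base * exp(sigma * stats::rnorm(length(tt)))
  out
}
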
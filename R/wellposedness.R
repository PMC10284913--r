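#' Caputo-Fabrizio fixed-point coefficients
#'
#' The existence/uniqueness theory for the fractional growth models rewrites
#' the Caputo-Fabrizio integral form of \eqn{D^\alpha v = F(t, v)} as
#' \eqn{v(t) = v(0) + \phi(\alpha) F(t, v(t)) + \psi(\alpha) \int_0^t F},
#' with
#' \deqn{\phi(\alpha) = \frac{2 - 2\alpha}{M(\alpha)(2-\alpha)}, \qquad
#'       \psi(\alpha) = \frac{2\alpha}{(2-\alpha) M(\alpha)},}
#' where \eqn{M(\alpha)} is the Caputo-Fabrizio normalization constant
#' (taken as 1 by default, the common convention). \eqn{\phi(1) = 0}
#' exactly: at integer order the pointwise term vanishes.
#'
#' @param alpha fractional order in (0, 1].
#' @param M_alpha normalization constant \eqn{M(\alpha) > 0} (default 1).
#' @return named numeric vector \code{c(phi = , psi = )}.
#' @examples
#' phi_psi(0.97)  # phi = 0.0583, psi = 1.8835
#' @export
phi_psi <- function(alpha, M_alpha = 1) {
  stopifnot(alpha > 0, alpha <= 1, M_alpha > 0)
  c(phi = (2 - 2 * alpha) / (M_alpha * (2 - alpha)),
    psi = 2 * alpha / ((2 - alpha) * M_alpha))
}

#' Lipschitz constant of a growth law on a volume range
#'
#' The fixed-point conditions need a Lipschitz constant \eqn{\theta} of the
#' growth-rate function: \eqn{|f(v_1) - f(v_2)| \le \theta |v_1 - v_2|}.
#' For the exponential law the rate is linear and \eqn{\theta = a} exactly.
#' For the other laws \eqn{\theta} is estimated as the supremum of the
#' numerical derivative \eqn{|\partial f/\partial v|} (central differences)
#' over a dense grid on \code{v_range}.
#'
#' The particular Bertalanffy-Putter law has an unbounded derivative as
#' \eqn{v \to 0^+} when its exponent is below 1; its range must start at a
#' strictly positive volume (the pipeline default floor is 1e-3 model
#' units).
#'
#' @param model a [growth_model()].
#' @param v_range numeric length-2 interval of volumes (model units).
#' @param n_grid number of grid points for the numerical supremum.
#' @return the estimated Lipschitz constant \eqn{\theta \ge 0}.
#' @export
lipschitz_theta <- function(model, v_range = c(0, 20), n_grid = 2001L) {
  stopifnot(inherits(model, "growth_model"), length(v_range) == 2L,
            v_range[1] < v_range[2])
  if (model$kind == "exponential") return(model$params$a)
  lo <- v_range[1]
  if (model$kind == "bp_particular" && lo <= 0)
    stop("bp_particular needs a strictly positive lower volume bound",
         call. = FALSE)
  if (model$kind == "gompertz" && lo + model$params$c <= 0)
    stop("gompertz range violates v + c > 0", call. = FALSE)
  v <- seq(lo, v_range[2], length.out = n_grid)
  eps <- max(diff(v_range) * 1e-7, 1e-10)
  vl <- pmax(v - eps, lo)
  vr <- pmin(v + eps, v_range[2])
  d <- abs(growth_rate(model, vr) - growth_rate(model, vl)) / (vr - vl)
  max(d)
}

#' Existence condition for the fractional growth model
#'
#' The fixed-point argument guarantees a solution when
#' \eqn{(\phi(\alpha) + \psi(\alpha)\, c)\, \theta < 1} for some constant
#' \eqn{c}. The condition is monotone: increasing \eqn{\theta} or \eqn{c}
#' can only break it, never restore it.
#'
#' @param alpha fractional order in (0, 1].
#' @param theta Lipschitz constant of the growth law.
#' @param c_bound the constant \eqn{c} in the condition (default 1).
#' @param M_alpha normalization constant (default 1).
#' @param value if TRUE, return the condition value
#'   \eqn{(\phi + \psi c)\theta} instead of the boolean.
#' @return logical (condition holds) or the numeric condition value.
#' @examples
#' existence_check(0.97, theta = 0.046)                 # TRUE
#' existence_check(0.97, theta = 0.046, value = TRUE)   # 0.08932
#' @export
existence_check <- function(alpha, theta, c_bound = 1, M_alpha = 1,
                            value = FALSE) {
  stopifnot(theta >= 0, c_bound >= 0)
  pp <- phi_psi(alpha, M_alpha)
  val <- (pp[["phi"]] + pp[["psi"]] * c_bound) * theta
  if (value) val else val < 1
}

#' Uniqueness condition for the fractional growth model
#'
#' The solution is unique when
#' \eqn{1 - (\phi(\alpha) + \psi(\alpha)\, t)\, \theta > 0}, with \eqn{t}
#' the time horizon entering the contraction bound. At \eqn{t = 0} this
#' coincides with [existence_check()] at \eqn{c = 0} (both reduce to
#' \eqn{\phi\theta} comparisons).
#'
#' @param alpha fractional order in (0, 1].
#' @param theta Lipschitz constant of the growth law.
#' @param t_bound time horizon \eqn{t} in the condition.
#' @param M_alpha normalization constant (default 1).
#' @param value if TRUE, return \eqn{1 - (\phi + \psi t)\theta}.
#' @return logical (condition holds) or the numeric condition value.
#' @export
uniqueness_check <- function(alpha, theta, t_bound, M_alpha = 1,
                             value = FALSE) {
  stopifnot(theta >= 0, t_bound >= 0)
  pp <- phi_psi(alpha, M_alpha)
  val <- 1 - (pp[["phi"]] + pp[["psi"]] * t_bound) * theta
  if (value) val else val > 0
}

#' Mittag-Leffler stability classification of the linear model
#'
#' Classifies the long-time behavior of the fractional exponential model
#' \eqn{D^\alpha v = a v}, whose solution envelope is
#' \eqn{v_0 E_\alpha(a t^\alpha)}: growth rates \eqn{a > 0} give unbounded
#' growth, \eqn{a < 0} gives algebraic Mittag-Leffler decay to zero, and
#' \eqn{a = 0} a constant (bounded) solution. The classification is backed
#' by evaluating the solution envelope at \eqn{t \in \{10, 100, 1000\}}
#' rather than asserted from the sign alone.
#'
#' @param alpha fractional order in (0, 1].
#' @param a linear growth rate.
#' @return a list of class \code{"ml_stability"}: \code{classification}
#'   (one of \code{"decaying"}, \code{"bounded_convergent"},
#'   \code{"unbounded_growth"}), the probe times and the solution envelope
#'   \code{v(t)/v(0)} at them.
#' @examples
#' ml_stability_report(0.9, a = -0.5)   # decaying
#' @export
ml_stability_report <- function(alpha, a) {
  stopifnot(alpha > 0, alpha <= 1, is.finite(a))
  probes <- c(10, 100, 1000)
  env <- vapply(probes, function(t) {
    z <- a * t^alpha
    if (z > 30) Inf else mittag_leffler(alpha, z)
  }, numeric(1))
  classification <-
    if (a == 0) "bounded_convergent"
    else if (a < 0 && all(diff(env) < 0) && env[3] < env[1]) "decaying"
    else if (a > 0 && all(diff(env[is.finite(env)]) > 0)) "unbounded_growth"
    else "bounded_convergent"
  structure(list(classification = classification, alpha = alpha, a = a,
                 probe_times = probes, envelope = env),
            class = "ml_stability")
}

#' @export
print.ml_stability <- function(x, ...) {
  cat("Mittag-Leffler stability of D^", format(x$alpha), " v = ",
      format(x$a), " v: ", x$classification, "\n", sep = "")
  cat("  v(t)/v(0) at t = {10, 100, 1000}: ",
      paste(format(x$envelope, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Well-posedness report for a fitted growth model
#'
#' Bundles the fixed-point diagnostics for one model at one fractional
#' order: \eqn{\phi}, \eqn{\psi}, the Lipschitz constant \eqn{\theta} on
#' the stated volume range, the existence and uniqueness condition values,
#' and (for the exponential law) the Mittag-Leffler stability class.
#'
#' @param model a [growth_model()].
#' @param alpha fractional order in (0, 1].
#' @param v_range volume range for the Lipschitz estimate (model units);
#'   default \code{c(0, 20)}, i.e. up to the 2000 mm^3 censoring threshold.
#' @param c_bound constant in the existence condition (default 1).
#' @param t_bound horizon in the uniqueness condition (default 18 days).
#' @param M_alpha normalization constant (default 1).
#' @return a list of class \code{"wellposedness_report"}.
#' @export
wellposedness_report <- function(model, alpha, v_range = c(0, 20),
                                 c_bound = 1, t_bound = 18, M_alpha = 1) {
  if (model$kind %in% c("bp_particular") && v_range[1] <= 0)
    v_range[1] <- 1e-3
  theta <- lipschitz_theta(model, v_range)
  pp <- phi_psi(alpha, M_alpha)
  rep <- list(kind = model$kind, alpha = alpha, M_alpha = M_alpha,
              phi = pp[["phi"]], psi = pp[["psi"]], theta = theta,
              v_range = v_range, c_bound = c_bound, t_bound = t_bound,
              existence_value = existence_check(alpha, theta, c_bound,
                                                M_alpha, value = TRUE),
              existence_ok = existence_check(alpha, theta, c_bound, M_alpha),
              uniqueness_value = uniqueness_check(alpha, theta, t_bound,
                                                  M_alpha, value = TRUE),
              uniqueness_ok = uniqueness_check(alpha, theta, t_bound,
                                               M_alpha),
              stability = if (model$kind == "exponential")
                ml_stability_report(alpha, model$params$a)$classification)
  structure(rep, class = "wellposedness_report")
}

#' @export
print.wellposedness_report <- function(x, ...) {
  cat("Well-posedness [", x$kind, ", alpha = ", format(x$alpha), "]:\n",
      sep = "")
  cat(sprintf("  phi = %.6g, psi = %.6g, theta = %.6g on [%g, %g]\n",
              x$phi, x$psi, x$theta, x$v_range[1], x$v_range[2]))
  cat(sprintf("  existence  (phi + psi c) theta = %.5g  -> %s (c = %g)\n",
              x$existence_value, if (x$existence_ok) "holds" else "fails",
              x$c_bound))
  cat(sprintf("  uniqueness 1 - (phi + psi t) theta = %.5g -> %s (t = %g)\n",
              x$uniqueness_value, if (x$uniqueness_ok) "holds" else "fails",
              x$t_bound))
  if (!is.null(x$stability))
    cat("  Mittag-Leffler stability class:", x$stability, "\n")
  invisible(x)
}
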
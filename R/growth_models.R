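#' Tumor growth-law specification
#'
#' Constructs one of the five growth laws used throughout the package,
#' validated against its parameter constraints. Volumes are in model volume
#' units (1 unit = 100 mm^3, see [simulate_experiment()]); rates carry
#' implied units day^-alpha when used fractionally.
#'
#' The laws and their parameters:
#' \describe{
#'   \item{exponential}{\eqn{dv/dt = a v}; \code{a} growth exponent.}
#'   \item{logistic}{\eqn{dv/dt = a v (1 - (v/k)^b)}; \code{a} inherent
#'     growth rate, \code{k} carrying capacity, \code{b} rate-correcting
#'     exponent.}
#'   \item{gompertz}{\eqn{dv/dt = a v \ln(b/(v+c))}; \code{c} offsets the
#'     minimum carrying capacity. Two published forms circulate, with and
#'     without the leading \eqn{v} factor; both are supported through
#'     \code{gompertz_form} ("with_v" / "without_v", the latter being
#'     \eqn{dv/dt = a \ln(b/(v+c))}).}
#'   \item{bp_general}{Bertalanffy-Putter \eqn{dv/dt = p v^a - q v^b},
#'     \eqn{a \ne b}; \code{p} intrinsic growth, \code{q} antiangiogenic
#'     decline factor.}
#'   \item{bp_particular}{the \eqn{a = b} limit
#'     \eqn{dv/dt = p v^a - \ln(v)\, q v^a}, requiring \eqn{v > 0}.}
#' }
#'
#' All parameters must be strictly positive. \code{bp_general} with
#' \eqn{|a - b| < 10^{-6}} is rejected rather than silently switched to the
#' particular form: the two branches are distinct fitted models.
#'
#' @param law one of \code{"exponential"}, \code{"logistic"},
#'   \code{"gompertz"}, \code{"bp_general"}, \code{"bp_particular"}.
#'   (Named \code{law} rather than \code{kind} so that the logistic
#'   parameter \code{k} cannot partially match it.)
#' @param ... named numeric parameters for the chosen kind (see Details).
#' @param gompertz_form for \code{kind = "gompertz"}: \code{"with_v"}
#'   (default) or \code{"without_v"}.
#' @return an object of class \code{"growth_model"}.
#' @examples
#' growth_model("logistic", a = 0.0735, k = 2.81, b = 3.35)
#' growth_model("gompertz", a = 0.106, b = 26.09, c = 2.24,
#'              gompertz_form = "without_v")
#' @export
growth_model <- function(law = c("exponential", "logistic", "gompertz",
                                 "bp_general", "bp_particular"),
                         ..., gompertz_form = c("with_v", "without_v")) {
  kind <- match.arg(law)
  gompertz_form <- match.arg(gompertz_form)
  params <- list(...)
  wanted <- model_param_names(kind)
  if (!setequal(names(params), wanted))
    stop(kind, " model requires exactly the parameters: ",
         paste(wanted, collapse = ", "), call. = FALSE)
  params <- lapply(params[wanted], as.numeric)
  bad <- vapply(params, function(p) !is.finite(p) || p <= 0, logical(1))
  if (any(bad))
    stop("all growth-law parameters must be positive and finite; offending: ",
         paste(wanted[bad], collapse = ", "), call. = FALSE)
  if (kind == "bp_general" && abs(params$a - params$b) < 1e-6)
    stop("bp_general requires a != b; use kind = 'bp_particular' for a = b",
         call. = FALSE)
  structure(list(kind = kind, params = params,
                 gompertz_form = if (kind == "gompertz") gompertz_form),
            class = "growth_model")
}

model_param_names <- function(kind) {
  switch(kind,
         exponential   = "a",
         logistic      = c("a", "k", "b"),
         gompertz      = c("a", "b", "c"),
         bp_general    = c("p", "q", "a", "b"),
         bp_particular = c("p", "q", "a"))
}

#' @export
print.growth_model <- function(x, ...) {
  p <- x$params
  eq <- switch(x$kind,
    exponential   = sprintf("dv/dt = %g v", p$a),
    logistic      = sprintf("dv/dt = %g v (1 - (v/%g)^%g)", p$a, p$k, p$b),
    gompertz      = if (identical(x$gompertz_form, "without_v"))
                      sprintf("dv/dt = %g ln(%g/(v + %g))", p$a, p$b, p$c)
                    else
                      sprintf("dv/dt = %g v ln(%g/(v + %g))", p$a, p$b, p$c),
    bp_general    = sprintf("dv/dt = %g v^%g - %g v^%g", p$p, p$a, p$q, p$b),
    bp_particular = sprintf("dv/dt = %g v^%g - ln(v) %g v^%g",
                            p$p, p$a, p$q, p$a))
  cat("Growth law [", x$kind, "]: ", eq, "\n", sep = "")
  invisible(x)
}

#' Growth rate of a model at given volumes
#'
#' Evaluates the right-hand side \eqn{f(v)} of a growth law, vectorized over
#' \code{v}. Domain checks follow the law: volumes must be non-negative,
#' \eqn{v + c > 0} for Gompertz, and \eqn{v > 0} for the particular
#' Bertalanffy-Putter form (its \eqn{\ln v} term).
#'
#' @param model a [growth_model()].
#' @param v numeric vector of volumes (model units).
#' @return numeric vector of growth rates, same length as \code{v}.
#' @examples
#' m <- growth_model("exponential", a = 0.046)
#' growth_rate(m, c(0, 1, 2))
#' @export
growth_rate <- function(model, v) {
  stopifnot(inherits(model, "growth_model"), is.numeric(v))
  p <- model$params
  switch(model$kind,
    exponential = {
      if (any(v < 0)) stop("exponential law requires v >= 0", call. = FALSE)
      p$a * v
    },
    logistic = {
      if (any(v < 0)) stop("logistic law requires v >= 0", call. = FALSE)
      p$a * v * (1 - (v / p$k)^p$b)
    },
    gompertz = {
      if (any(v + p$c <= 0))
        stop("gompertz law requires v + c > 0", call. = FALSE)
      if (identical(model$gompertz_form, "without_v"))
        p$a * log(p$b / (v + p$c))
      else
        p$a * v * log(p$b / (v + p$c))
    },
    bp_general = {
      if (any(v < 0)) stop("bp_general law requires v >= 0", call. = FALSE)
      p$p * v^p$a - p$q * v^p$b
    },
    bp_particular = {
      if (any(v <= 0))
        stop("bp_particular law requires v > 0 (ln v term)", call. = FALSE)
      p$p * v^p$a - log(v) * p$q * v^p$a
    })
}

#' Analytic solution of the fractional exponential model
#'
#' \eqn{D^\alpha v = a v}, \eqn{v(0) = v_0} has the closed-form solution
#' \eqn{v(t) = v_0\, E_\alpha(a t^\alpha)} in terms of the Mittag-Leffler
#' function; at \eqn{\alpha = 1} this reduces to \eqn{v_0 e^{a t}}. Used as
#' the independent reference for the numerical fractional solver.
#'
#' @param t time(s) in days, >= 0.
#' @param a growth rate (> 0 for growth, < 0 for decay).
#' @param alpha fractional order in (0, 1].
#' @param v0 initial volume.
#' @return numeric vector of volumes.
#' @export
ml_exponential <- function(t, a, alpha = 1, v0 = 1) {
  stopifnot(all(t >= 0), alpha > 0, alpha <= 1)
  v0 * mittag_leffler(alpha, a * t^alpha)
}

#' Closed-form integer-order solutions
#'
#' Textbook solutions of the integer-order (\eqn{\alpha = 1}) growth laws,
#' used as solver oracles: exponential \eqn{v_0 e^{at}} and generalized
#' logistic (Richards) \eqn{k\,[1 + ((k/v_0)^b - 1) e^{-abt}]^{-1/b}}.
#' The remaining laws (Gompertz with its carrying-capacity offset and the
#' Bertalanffy-Putter pair) have no elementary closed form and signal a
#' not-available error; they are cross-checked numerically instead.
#'
#' @param model a [growth_model()].
#' @param v0 initial volume > 0.
#' @param times numeric vector of days.
#' @return a [trajectory()] on \code{times}.
#' @export
analytic_integer_solution <- function(model, v0, times) {
  stopifnot(inherits(model, "growth_model"), v0 > 0)
  p <- model$params
  v <- switch(model$kind,
    exponential = v0 * exp(p$a * times),
    logistic = p$k / (1 + ((p$k / v0)^p$b - 1) * exp(-p$a * p$b * times))^(1 / p$b),
    stop("no closed form available for kind '", model$kind, "'",
         call. = FALSE))
  trajectory(times, v)
}
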
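#' Tumor-volume trajectory
#'
#' Light container for a solved or measured tumor-volume time course:
#' strictly increasing times (days) paired with non-negative volumes.
#' Returned by [solve_caputo_ivp()] and accepted throughout the package.
#'
#' @param times numeric vector of days, strictly increasing, first >= 0.
#' @param volumes numeric vector of volumes, same length, finite, >= 0.
#' @return a data.frame with columns \code{time}, \code{volume} and class
#'   \code{"trajectory"}.
#' @export
trajectory <- function(times, volumes) {
  stopifnot(is.numeric(times), is.numeric(volumes))
  if (length(times) != length(volumes))
    stop("times and volumes must have equal length", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(volumes)))
    stop("trajectory values must be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (times[1] < 0) stop("times must start at >= 0", call. = FALSE)
  if (any(volumes < 0)) stop("volumes must be non-negative", call. = FALSE)
  structure(data.frame(time = as.numeric(times), volume = as.numeric(volumes)),
            class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Tumor-volume trajectory:", nrow(x), "points on [",
      format(x$time[1]), ",", format(x$time[nrow(x)]), "] days\n")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

# uniform-grid guard shared by the quadratures below
check_uniform <- function(times, what = "grid") {
  h <- diff(times)
  if (length(h) < 1 || any(h <= 0) ||
      max(abs(h - h[1])) > 1e-8 * max(h[1], 1))
    stop(what, " must be a uniform, increasing time grid", call. = FALSE)
  h[1]
}

#' Riemann-Liouville fractional integral of sampled data
#'
#' Computes \eqn{I^\alpha f(t) = \frac{1}{\Gamma(\alpha)} \int_0^t
#' (t-\tau)^{\alpha-1} f(\tau)\, d\tau} by product-trapezoidal quadrature:
#' \code{f} is taken piecewise linear between the grid points and the weakly
#' singular kernel is integrated exactly on each panel, so the rule is exact
#' for linear integrands and second-order accurate otherwise.
#'
#' @param f either a function of one variable or a numeric vector of samples
#'   on the uniform grid \code{seq(0, by = h, length.out = length(f))}.
#' @param alpha integration order, > 0.
#' @param t evaluation time; must be a grid point within the sampled range.
#' @param h grid step (days); required when \code{f} is a vector, otherwise
#'   the sampling step used for \code{f}.
#' @return the scalar value of the fractional integral at \code{t}.
#' @examples
#' rl_integral(function(x) rep(1, length(x)), alpha = 0.5, t = 1, h = 0.001)
#' # closed form: t^alpha / gamma(alpha + 1) = 1/gamma(1.5) = 1.128379...
#' @export
rl_integral <- function(f, alpha, t, h = 0.01) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(t), length(t) == 1L, t > 0, h > 0)
  n <- round(t / h)
  if (abs(n * h - t) > 1e-8 * max(t, 1))
    stop("t must lie on the sampling grid (a multiple of h)", call. = FALSE)
  grid <- seq(0, by = h, length.out = n + 1L)
  if (is.function(f)) {
    fv <- f(grid)
    if (length(fv) == 1L) fv <- rep(fv, n + 1L)
  } else {
    fv <- as.numeric(f)
    if (length(fv) < n + 1L)
      stop("samples do not cover [0, t]", call. = FALSE)
    fv <- fv[seq_len(n + 1L)]
  }
  if (n == 0L) return(0)
  # product-trapezoid weights: h^a/Gamma(a+2) * a_j, the classical corrector
  # weights of the Adams scheme for the same kernel
  w <- corrector_weights(n, alpha)
  h^alpha / gamma(alpha + 2) * sum(w * fv)
}

# weights a_{j,n} for j = 0..n of the product-trapezoid rule on [0, t_n]
corrector_weights <- function(n, alpha) {
  j <- 0:n
  if (n == 1L) return(c(alpha, 1))  # a_0 = n^{a+1} - (n-a)(n+1)^a at n=1... see below
  a <- numeric(n + 1L)
  a[1] <- (n - 1)^(alpha + 1) - (n - 1 - alpha) * n^alpha
  m <- (n - j[2:n])  # for j = 1..n-1: m = n-j in 1..n-1
  a[2:n] <- (m + 1)^(alpha + 1) + (m - 1)^(alpha + 1) - 2 * m^(alpha + 1)
  a[n + 1L] <- 1
  a
}

#' Caputo fractional derivative of sampled data (L1 scheme)
#'
#' Discretizes \eqn{D^\alpha f(t) = \frac{1}{\Gamma(1-\alpha)} \int_0^t
#' \frac{f'(\tau)}{(t-\tau)^{\alpha}}\, d\tau} for \eqn{0 < \alpha < 1} with
#' the L1 finite-difference scheme (piecewise-linear \code{f}, exact kernel
#' integration). The scheme inherits the defining Caputo property that the
#' derivative of a constant is identically zero, and is exact for linear
#' \code{f}.
#'
#' @param f numeric vector of samples on the uniform grid \code{times}.
#' @param alpha derivative order in (0, 1).
#' @param times uniform, strictly increasing grid with at least 3 points.
#' @return numeric vector of the derivative at each grid point (0 at t = 0).
#' @examples
#' tt <- seq(0, 1, by = 0.01)
#' d <- caputo_derivative(tt, alpha = 0.5, times = tt)
#' d[length(d)]  # closed form t^{0.5}/gamma(1.5) at t = 1: 1.128379...
#' @export
caputo_derivative <- function(f, alpha, times) {
  stopifnot(is.numeric(f), is.numeric(times), length(f) == length(times))
  if (length(times) < 3L) stop("need at least 3 grid points", call. = FALSE)
  if (!(alpha > 0 && alpha < 1))
    stop("alpha must lie in (0, 1)", call. = FALSE)
  h <- check_uniform(times)
  n_pts <- length(times)
  df <- diff(f)
  # b_j = (j+1)^{1-a} - j^{1-a}, j = 0..n-1
  b <- (seq_len(n_pts)^(1 - alpha) - (seq_len(n_pts) - 1)^(1 - alpha))
  out <- numeric(n_pts)
  coef <- h^(-alpha) / gamma(2 - alpha)
  for (n in seq_len(n_pts - 1L)) {
    out[n + 1L] <- coef * sum(b[n:1] * df[1:n])
  }
  out
}

#' Solve a Caputo fractional initial-value problem
#'
#' Integrates \eqn{D^\alpha v = f(t, v)}, \eqn{v(0) = v_0}, with the
#' fractional Adams-Bashforth-Moulton predictor-corrector (fractional Euler
#' predictor, product-trapezoid corrector, full memory term). At
#' \eqn{\alpha = 1} the scheme reduces to the classical second-order
#' Adams predictor-corrector pair, so integer-order trajectories are
#' obtained from the same code path. Cost is \eqn{O(N^2)} in the number of
#' grid points because every step carries the full Caputo memory.
#'
#' @param rhs function \code{(t, v)} returning the growth rate, or a
#'   [growth_model()] object (its rate law is used).
#' @param alpha fractional order in (0, 1].
#' @param v0 initial volume, >= 0.
#' @param times uniform, strictly increasing grid starting at the initial
#'   time (taken as 0 for the Caputo memory).
#' @param corrector_iters number of corrector passes (>= 1, default 1).
#' @param nonneg if TRUE, abort with a solver-divergence error as soon as the
#'   state goes negative (tumor volumes must stay >= 0).
#' @return a [trajectory()] on \code{times}.
#' @examples
#' tr <- solve_caputo_ivp(function(t, v) 0.109 * v, alpha = 0.98, v0 = 1,
#'                        times = seq(0, 18, by = 0.05))
#' tail(tr, 1)  # close to mittag_leffler(0.98, 0.109 * 18^0.98)
#' @export
solve_caputo_ivp <- function(rhs, alpha, v0, times, corrector_iters = 1L,
                             nonneg = FALSE) {
  if (inherits(rhs, "growth_model")) {
    model <- rhs
    rhs <- function(t, v) growth_rate(model, v)
  }
  stopifnot(is.function(rhs), is.numeric(v0), length(v0) == 1L, v0 >= 0,
            corrector_iters >= 1L)
  if (!(alpha > 0 && alpha <= 1))
    stop("alpha must lie in (0, 1]", call. = FALSE)
  h <- check_uniform(times)
  n_pts <- length(times)
  N <- n_pts - 1L
  m <- 0:(N + 1L)
  pa <- m^alpha
  pb <- m^(alpha + 1)
  # predictor increments: dif[k] = k^a - (k-1)^a, k = 1..N+1
  dif <- pa[-1] - pa[-length(pa)]
  # interior corrector weights d2[m] = (m+1)^{a+1} + (m-1)^{a+1} - 2 m^{a+1}
  d2 <- pb[3:(N + 2L)] + pb[1:N] - 2 * pb[2:(N + 1L)]
  ha1 <- h^alpha / gamma(alpha + 1)
  ha2 <- h^alpha / gamma(alpha + 2)
  v <- numeric(n_pts)
  fv <- numeric(n_pts)
  v[1] <- v0
  fv[1] <- rhs(times[1], v0)
  for (n in 0:(N - 1L)) {
    fh <- fv[1:(n + 1L)]
    vp <- v0 + ha1 * sum(dif[(n + 1L):1] * fh)
    a0 <- pb[n + 1L] - (n - alpha) * pa[n + 2L]
    w <- if (n >= 1L) c(a0, d2[n:1]) else a0
    s_mem <- sum(w * fh)
    vn <- v0 + ha2 * (rhs(times[n + 2L], vp) + s_mem)
    if (corrector_iters > 1L) {
      for (it in seq_len(corrector_iters - 1L))
        vn <- v0 + ha2 * (rhs(times[n + 2L], vn) + s_mem)
    }
    if (!is.finite(vn)) {
      stop(solver_divergence_error(times[n + 1L]))
    }
    if (nonneg && vn < 0) {
      stop(solver_divergence_error(
        times[n + 1L],
        msg = "state went negative (tumor volume must stay >= 0)"))
    }
    v[n + 2L] <- vn
    fv[n + 2L] <- rhs(times[n + 2L], vn)
    if (!is.finite(fv[n + 2L])) stop(solver_divergence_error(times[n + 2L]))
  }
  trajectory(times, v)
}

solver_divergence_error <- function(last_t, msg = "trajectory blew up") {
  structure(
    class = c("fractumor_solver_divergence", "error", "condition"),
    list(message = paste0("fractional IVP solver diverged: ", msg,
                          "; last valid time t = ", format(last_t)),
         call = NULL, last_valid_time = last_t))
}
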
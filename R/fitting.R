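#' Resample sparse measurements onto a uniform grid by cubic spline
#'
#' Tumor volumes are measured every few days; model identification works on
#' a dense uniform grid. This interpolates the measurements with a cubic
#' spline (Forsythe-Malcolm-Moler end conditions), which passes through
#' every measurement exactly, and evaluates it on a uniform grid spanning
#' the measured range. No extrapolation beyond the first or last
#' measurement is performed.
#'
#' @param times measurement days, strictly increasing, at least 4 points.
#' @param volumes measured volumes, same length.
#' @param step grid step in days (default 0.1).
#' @return a [trajectory()] on \code{seq(min(times), max(times), by = step)}.
#' @export
spline_resample <- function(times, volumes, step = 0.1) {
  stopifnot(is.numeric(times), is.numeric(volumes),
            length(times) == length(volumes), step > 0)
  if (length(times) < 4L)
    stop("spline resampling needs at least 4 measurement points",
         call. = FALSE)
  if (any(diff(times) <= 0))
    stop("measurement times must be strictly increasing", call. = FALSE)
  sf <- stats::splinefun(times, volumes, method = "fmm")
  grid <- seq(times[1], times[length(times)], by = step)
  # keep the last measurement on the grid when step does not divide the span
  if (grid[length(grid)] < times[length(times)] - 1e-9)
    grid <- c(grid, times[length(times)])
  trajectory(grid, pmax(sf(grid), 0))
}

#' Mean squared error between two aligned trajectories
#'
#' \eqn{\mathrm{MSE} = \frac{1}{n} \sum_i (y_i - \hat y_i)^2}, the sole
#' model-comparison statistic used by the fitting pipeline.
#'
#' @param observed,predicted trajectories (or plain numeric vectors) on the
#'   same time grid.
#' @return non-negative scalar; zero iff the inputs are identical.
#' @export
mse <- function(observed, predicted) {
  oy <- traj_values(observed)
  py <- traj_values(predicted)
  if (length(oy) != length(py))
    stop("MSE requires equal-length, aligned series", call. = FALSE)
  if (inherits(observed, "trajectory") && inherits(predicted, "trajectory") &&
      max(abs(observed$time - predicted$time)) > 1e-8)
    stop("MSE requires trajectories on identical time grids", call. = FALSE)
  mean((oy - py)^2)
}

traj_values <- function(x) {
  if (inherits(x, "trajectory") || is.data.frame(x)) x$volume else as.numeric(x)
}

# solve a growth model on the (possibly offset) uniform data grid;
# the Caputo memory is based at the first grid point
solve_on_grid <- function(model, alpha, v0, times, nonneg = TRUE) {
  tr <- solve_caputo_ivp(model, alpha = alpha, v0 = v0,
                         times = times - times[1], nonneg = nonneg)
  trajectory(times, tr$volume)
}

#' Fit a growth law at integer order by Nelder-Mead
#'
#' Minimizes the mean squared error between the model trajectory at
#' \eqn{\alpha = 1} and the (resampled) data over the law's kinetic
#' parameters, using the Nelder-Mead simplex on log-transformed parameters
#' (which enforces positivity without constraints). The initial volume is
#' fixed to the first observation and is not a free parameter. A second
#' Nelder-Mead run restarted from the first optimum guards against
#' premature simplex collapse. Parameter trials on which the solver
#' diverges score \code{+Inf} and the search continues.
#'
#' @param kind growth-law kind (see [growth_model()]).
#' @param data a uniform-grid [trajectory()] in model volume units,
#'   typically from [spline_resample()].
#' @param init named vector/list of strictly positive starting parameters
#'   for the kind.
#' @param gompertz_form Gompertz variant, see [growth_model()].
#' @param control list overriding optimizer settings: \code{reltol}
#'   (default 1e-10), \code{maxit} (default 2000), \code{restarts}
#'   (default 1 extra run).
#' @return an object of class \code{"fit_result"}: the fitted
#'   [growth_model()], \code{alpha = 1}, the attained \code{mse}, the
#'   number of objective evaluations, a convergence flag and the fixed
#'   \code{v0}.
#' @export
fit_integer <- function(kind, data, init,
                        gompertz_form = c("with_v", "without_v"),
                        control = list()) {
  gompertz_form <- match.arg(gompertz_form)
  stopifnot(inherits(data, "trajectory") || is.data.frame(data))
  check_uniform(data$time, "fitting data")
  ctrl <- utils::modifyList(
    list(reltol = 1e-10, maxit = 2000L, restarts = 1L), control)
  pnames <- model_param_names(kind)
  init <- unlist(init)[pnames]
  if (anyNA(init) || any(init <= 0))
    stop("init must supply strictly positive values for: ",
         paste(pnames, collapse = ", "), call. = FALSE)
  v0 <- data$volume[1]
  n_eval <- 0L
  objective <- function(logp) {
    n_eval <<- n_eval + 1L
    p <- as.list(exp(logp))
    names(p) <- pnames
    tryCatch({
      m <- do.call(growth_model,
                   c(list(law = kind), p,
                     if (kind == "gompertz") list(gompertz_form = gompertz_form)))
      pred <- solve_on_grid(m, alpha = 1, v0 = v0, times = data$time)
      val <- mse(data, pred)
      if (!is.finite(val)) Inf else val
    }, error = function(e) Inf)
  }
  par <- log(init)
  conv <- FALSE
  for (run in seq_len(1L + ctrl$restarts)) {
    opt <- suppressWarnings(stats::optim(
      par, objective, method = "Nelder-Mead",
      control = list(reltol = ctrl$reltol, maxit = ctrl$maxit)))
    par <- opt$par
    conv <- opt$convergence == 0L
  }
  best <- as.list(exp(par))
  names(best) <- pnames
  model <- do.call(growth_model,
                   c(list(law = kind), best,
                     if (kind == "gompertz") list(gompertz_form = gompertz_form)))
  structure(list(model = model, alpha = 1, mse = opt$value,
                 n_evaluations = n_eval, converged = conv, v0 = v0),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit (alpha = ", format(x$alpha), "): MSE = ",
      format(x$mse, digits = 6), if (!x$converged) "  [not converged]",
      "\n", sep = "")
  print(x$model)
  invisible(x)
}

#' Fractional-order stage: one-dimensional search over alpha
#'
#' Second stage of the two-stage identification: the kinetic parameters are
#' frozen at their integer-order estimates and only the Caputo order
#' \eqn{\alpha} is varied over a grid. For each \eqn{\alpha} the fractional
#' trajectory is solved and scored by MSE; the reported optimum is the grid
#' arg-min (smallest \eqn{\alpha} on exact ties, so reports are
#' deterministic). Because the grid contains \eqn{\alpha = 1}, the
#' fractional MSE can never exceed the integer-order MSE computed on the
#' same grid. Orders at which the solver diverges score \code{+Inf} and are
#' flagged in the sweep.
#'
#' @param model a fitted [growth_model()] (parameters held fixed).
#' @param data the same uniform-grid [trajectory()] used for the integer
#'   fit.
#' @param alpha_grid increasing grid in (0, 1]; must contain 1.0.
#' @param v0 initial volume; defaults to the first observation.
#' @return a list with components \code{fit} (a \code{"fit_result"} at the
#'   optimal order) and \code{sweep} (class \code{"alpha_sweep"}: data.frame
#'   of \code{alpha}, \code{mse}, \code{ok}).
#' @export
fit_alpha <- function(model, data, alpha_grid = seq(0.7, 1, by = 0.01),
                      v0 = NULL) {
  stopifnot(inherits(model, "growth_model"))
  check_uniform(data$time, "fitting data")
  alpha_grid <- sort(unique(as.numeric(alpha_grid)))
  if (any(alpha_grid <= 0 | alpha_grid > 1))
    stop("alpha_grid must lie in (0, 1]", call. = FALSE)
  if (max(alpha_grid) < 1 - 1e-12)
    stop("alpha_grid must contain 1.0 (the integer-order anchor)",
         call. = FALSE)
  if (is.null(v0)) v0 <- data$volume[1]
  mses <- vapply(alpha_grid, function(a) {
    tryCatch({
      pred <- solve_on_grid(model, alpha = a, v0 = v0, times = data$time)
      val <- mse(data, pred)
      if (is.finite(val)) val else Inf
    }, error = function(e) Inf)
  }, numeric(1))
  ok <- is.finite(mses)
  if (!any(ok)) stop("fractional solver diverged at every alpha", call. = FALSE)
  i <- which(mses == min(mses))[1]  # smallest alpha among ties
  sweep <- structure(data.frame(alpha = alpha_grid, mse = mses, ok = ok),
                     class = c("alpha_sweep", "data.frame"),
                     argmin_alpha = alpha_grid[i])
  fit <- structure(list(model = model, alpha = alpha_grid[i], mse = mses[i],
                        n_evaluations = length(alpha_grid), converged = TRUE,
                        v0 = v0),
                   class = "fit_result")
  list(fit = fit, sweep = sweep)
}

#' @export
print.alpha_sweep <- function(x, ...) {
  cat("MSE-alpha sweep over", nrow(x), "orders; argmin alpha =",
      format(attr(x, "argmin_alpha")), "\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' MSE ratio of fractional vs integer fit, in percent
#'
#' \code{100 * fractional_mse / integer_mse}: the percentage of the
#' integer-order error retained by the fractional model (smaller is
#' better; 100 means no improvement).
#'
#' @param integer_mse,fractional_mse non-negative scalars.
#' @return the ratio in percent.
#' @examples
#' mse_reduction_percent(0.8557, 0.2243)  # 26.21...
#' @export
mse_reduction_percent <- function(integer_mse, fractional_mse) {
  stopifnot(integer_mse > 0, fractional_mse >= 0)
  100 * fractional_mse / integer_mse
}

#' Fit and compare all growth laws across datasets
#'
#' Runs the full two-stage identification ([fracfit()]) for every
#' combination of dataset and growth-law kind and tabulates integer MSE,
#' fractional MSE, the optimal order and the retained-MSE percentage.
#' A failed fit is recorded as a row of \code{NA}s with the error message;
#' the report is still produced.
#'
#' @param datasets named list of measurement sets (trajectories or
#'   data.frames with \code{time}, \code{volume}, in model volume units).
#' @param kinds character vector of growth-law kinds to fit.
#' @param alpha_grid,grid_step,gompertz_form,inits,control passed to
#'   [fracfit()]; \code{inits} may be a named list (per kind) of named
#'   parameter vectors.
#' @return a data.frame of class \code{"growth_comparison"} with columns
#'   \code{dataset}, \code{model}, \code{integer_mse}, \code{fractional_mse},
#'   \code{fractional_alpha}, \code{ratio_percent}, \code{converged},
#'   \code{error}.
#' @export
compare_models <- function(datasets,
                           kinds = c("exponential", "logistic", "gompertz",
                                     "bp_general", "bp_particular"),
                           alpha_grid = seq(0.7, 1, by = 0.01),
                           grid_step = 0.1,
                           gompertz_form = "with_v",
                           inits = NULL, control = list()) {
  stopifnot(is.list(datasets), length(names(datasets)) == length(datasets))
  rows <- list()
  for (ds in names(datasets)) {
    for (kind in kinds) {
      row <- tryCatch({
        fit <- fracfit(datasets[[ds]], kind = kind,
                       init = inits[[kind]],
                       alpha_grid = alpha_grid, grid_step = grid_step,
                       gompertz_form = gompertz_form, control = control)
        data.frame(dataset = ds, model = kind,
                   integer_mse = fit$integer$mse,
                   fractional_mse = fit$fractional$mse,
                   fractional_alpha = fit$fractional$alpha,
                   ratio_percent = mse_reduction_percent(
                     fit$integer$mse, fit$fractional$mse),
                   converged = fit$integer$converged,
                   error = NA_character_)
      }, error = function(e) {
        data.frame(dataset = ds, model = kind, integer_mse = NA_real_,
                   fractional_mse = NA_real_, fractional_alpha = NA_real_,
                   ratio_percent = NA_real_, converged = FALSE,
                   error = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("growth_comparison", "data.frame")
  out
}

#' @export
print.growth_comparison <- function(x, digits = 4, ...) {
  cat("Integer vs fractional growth-law comparison (MSE):\n")
  df <- as.data.frame(x)
  df$integer_mse <- signif(df$integer_mse, digits)
  df$fractional_mse <- signif(df$fractional_mse, digits)
  df$ratio_percent <- round(df$ratio_percent, 2)
  print.data.frame(df[, setdiff(names(df), "error")], row.names = FALSE)
  if (any(!is.na(df$error)))
    cat("failed fits:", sum(!is.na(df$error)), "(see $error)\n")
  invisible(x)
}
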
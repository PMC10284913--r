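#' Treatment protocol for simulated xenograft experiments
#'
#' Encodes the observation-driven dosing protocol the generator emulates:
#' drug is given when a measured volume reaches \code{dose_threshold} and at
#' least \code{min_dose_interval} days have passed since the last dose; the
#' experiment is stopped when a measurement reaches \code{stop_threshold};
#' volumes are observed for \code{horizon} days at a cadence alternating
#' between the values in \code{sampling_days}.
#'
#' @param dose_threshold trigger volume in mm^3 (default 200).
#' @param min_dose_interval minimum days between doses (default 10).
#' @param dose administered dose in mg/kg (default 8; recorded in the dose
#'   log, not used mechanistically -- the growth laws carry no drug term).
#' @param stop_threshold censoring volume in mm^3 (default 2000).
#' @param horizon observation horizon in days (default 18).
#' @param sampling_days alternating sampling intervals in days
#'   (default \code{c(2, 3)}).
#' @return a list of class \code{"treatment_protocol"}.
#' @export
treatment_protocol <- function(dose_threshold = 200, min_dose_interval = 10,
                               dose = 8, stop_threshold = 2000, horizon = 18,
                               sampling_days = c(2, 3)) {
  stopifnot(dose_threshold > 0, stop_threshold > dose_threshold,
            min_dose_interval > 0, min_dose_interval <= horizon,
            horizon > 0, all(sampling_days %in% c(1, 2, 3)))
  structure(list(dose_threshold = dose_threshold,
                 min_dose_interval = min_dose_interval, dose = dose,
                 stop_threshold = stop_threshold, horizon = horizon,
                 sampling_days = sampling_days),
            class = "treatment_protocol")
}

sample_times <- function(protocol) {
  tt <- 0
  k <- 0L
  repeat {
    nxt <- tt[length(tt)] +
      protocol$sampling_days[k %% length(protocol$sampling_days) + 1L]
    if (nxt > protocol$horizon) break
    tt <- c(tt, nxt)
    k <- k + 1L
  }
  tt
}

#' Simulate a treated or untreated tumor-volume experiment
#'
#' Generates one arm of a synthetic xenograft experiment: the chosen growth
#' law is integrated as a Caputo fractional initial-value problem, sampled
#' at the protocol's 2-3-day cadence, and perturbed by multiplicative
#' lognormal measurement noise (median 1). In the treated arm, each dose
#' applies an instantaneous log-kill -- the volume drops to
#' \eqn{(1-\kappa)} times its pre-dose value -- and the fractional solver
#' is restarted from the post-kill state (the Caputo memory is reset at
#' dose times). Dosing decisions are made from the *measured* (noisy)
#' values at sample times only, mirroring an observation-driven protocol;
#' the first measurement at or above the stop threshold is recorded and
#' ends the experiment.
#'
#' A dose with \eqn{\kappa = 0} leaves the state untouched and does not
#' restart the solver, so a treated arm with \eqn{\kappa = 0} reproduces
#' the untreated trajectory exactly under the same seed.
#'
#' Dynamics are computed in model volume units (1 unit =
#' \code{unit_factor} mm^3, default 100); measurements are reported in
#' mm^3.
#'
#' @param model a [growth_model()] (parameters in model volume units).
#' @param alpha Caputo order in (0, 1] (default 1, the classical model).
#' @param v0_mm3 initial volume in mm^3 (default 50).
#' @param protocol a [treatment_protocol()] for the treated arm, or
#'   \code{NULL} for the untreated arm (sampling then follows the default
#'   protocol cadence and horizon with no dosing).
#' @param kill_fraction instantaneous kill fraction \eqn{\kappa \in [0, 1)}
#'   per dose (default 0.4).
#' @param sigma relative measurement noise (lognormal scale, default 0.05;
#'   must be in [0, 0.5]).
#' @param seed integer seed; identical seeds give identical output.
#' @param solver_step dense integration step in days (default 0.01).
#' @param unit_factor mm^3 per model volume unit (default 100).
#' @return a list of class \code{"tumor_experiment"} with components
#'   \code{measurements} (data.frame \code{time_days}, \code{volume_mm3}),
#'   \code{doses} (dose times in days), \code{trajectory} (dense noise-free
#'   [trajectory()] in mm^3), and the generating configuration.
#' @examples
#' m <- growth_model("exponential", a = 0.109)
#' ex <- simulate_experiment(m, alpha = 1, v0_mm3 = 50, sigma = 0,
#'                           seed = 1)
#' ex$measurements
#' @export
simulate_experiment <- function(model, alpha = 1, v0_mm3 = 50,
                                protocol = NULL, kill_fraction = 0.4,
                                sigma = 0.05, seed = NULL,
                                solver_step = 0.01, unit_factor = 100) {
  stopifnot(inherits(model, "growth_model"), v0_mm3 > 0,
            kill_fraction >= 0, kill_fraction < 1,
            sigma >= 0, sigma <= 0.5)
  treated <- !is.null(protocol)
  if (is.null(protocol)) protocol <- treatment_protocol()
  stopifnot(inherits(protocol, "treatment_protocol"))
  if (!is.null(seed)) set.seed(seed)
  tt <- sample_times(protocol)
  noise_mult <- if (sigma > 0) exp(sigma * stats::rnorm(length(tt)))
                else rep(1, length(tt))

  solve_segment <- function(t0, v0_units) {
    grid <- seq(t0, protocol$horizon, by = solver_step)
    tr <- solve_caputo_ivp(model, alpha = alpha, v0 = v0_units,
                           times = grid - t0, nonneg = TRUE)
    trajectory(grid, tr$volume)
  }
  dense <- solve_segment(0, v0_mm3 / unit_factor)
  segments <- list()
  seg_start <- 1L
  doses <- numeric(0)
  last_dose <- -Inf
  meas_t <- numeric(0)
  meas_v <- numeric(0)
  for (i in seq_along(tt)) {
    v_true <- dense$volume[which.min(abs(dense$time - tt[i]))] * unit_factor
    v_meas <- v_true * noise_mult[i]
    meas_t <- c(meas_t, tt[i])
    meas_v <- c(meas_v, v_meas)
    if (v_meas >= protocol$stop_threshold) break  # censoring sample kept
    if (treated && v_meas >= protocol$dose_threshold &&
        tt[i] - last_dose >= protocol$min_dose_interval) {
      doses <- c(doses, tt[i])
      last_dose <- tt[i]
      if (kill_fraction > 0) {
        keep <- dense$time < tt[i] - 1e-9
        segments[[length(segments) + 1L]] <-
          as.data.frame(dense)[keep, , drop = FALSE]
        dense <- solve_segment(tt[i],
                               (1 - kill_fraction) * v_true / unit_factor)
      }
    }
  }
  segments[[length(segments) + 1L]] <-
    as.data.frame(dense)[dense$time <= meas_t[length(meas_t)] + 1e-9, ,
                         drop = FALSE]
  full <- do.call(rbind, segments)
  structure(list(measurements = data.frame(time_days = meas_t,
                                           volume_mm3 = meas_v),
                 doses = doses,
                 trajectory = trajectory(full$time,
                                         full$volume * unit_factor),
                 model = model, alpha = alpha, v0_mm3 = v0_mm3,
                 treated = treated, protocol = protocol,
                 kill_fraction = if (treated) kill_fraction else NA_real_,
                 sigma = sigma, seed = seed, unit_factor = unit_factor),
            class = "tumor_experiment")
}

#' @export
print.tumor_experiment <- function(x, ...) {
  cat("Synthetic tumor experiment [", x$model$kind,
      ", alpha = ", format(x$alpha),
      if (x$treated) ", treated" else ", untreated", "]\n", sep = "")
  cat("  ", nrow(x$measurements), " measurements over ",
      max(x$measurements$time_days), " days; noise sigma = ", x$sigma,
      "\n", sep = "")
  if (length(x$doses))
    cat("  doses at days:", paste(x$doses, collapse = ", "), "\n")
  print(x$measurements)
  invisible(x)
}

#' Convert mm^3 measurements to a model-unit trajectory
#'
#' @param x a \code{"tumor_experiment"} or a data.frame with
#'   \code{time_days} and \code{volume_mm3}.
#' @param unit_factor mm^3 per model volume unit (default 100).
#' @return a [trajectory()] in model volume units.
#' @export
as_model_units <- function(x, unit_factor = 100) {
  if (inherits(x, "tumor_experiment")) x <- x$measurements
  stopifnot(all(c("time_days", "volume_mm3") %in% names(x)))
  trajectory(x$time_days, x$volume_mm3 / unit_factor)
}

#' Write a seeded treated/untreated fixture pair to disk
#'
#' Generates one treated and one untreated measurement set from the same
#' growth law and writes them as CSV (\code{treated.csv},
#' \code{untreated.csv}; header \code{time_days,volume_mm3}, LF line
#' endings) together with a \code{manifest.json} recording the generating
#' truth: model kind and parameters, fractional order, seed, dose times,
#' kill fraction and noise level. Identical seeds produce byte-identical
#' files.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @param model generating [growth_model()] (default exponential with
#'   a = 0.109).
#' @param alpha generating fractional order (default 0.98).
#' @param v0_mm3,kill_fraction,sigma,protocol,solver_step passed to
#'   [simulate_experiment()] (treated arm uses \code{seed + 1}).
#' @return invisibly, a list with the two file paths and the manifest.
#' @export
make_fixture_pair <- function(dir, seed,
                              model = growth_model("exponential", a = 0.109),
                              alpha = 0.98, v0_mm3 = 50,
                              kill_fraction = 0.4, sigma = 0.05,
                              protocol = treatment_protocol(),
                              solver_step = 0.01) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  untreated <- simulate_experiment(model, alpha = alpha, v0_mm3 = v0_mm3,
                                   protocol = NULL, sigma = sigma,
                                   seed = seed, solver_step = solver_step)
  treated <- simulate_experiment(model, alpha = alpha, v0_mm3 = v0_mm3,
                                 protocol = protocol,
                                 kill_fraction = kill_fraction,
                                 sigma = sigma, seed = seed + 1L,
                                 solver_step = solver_step)
  paths <- c(treated = file.path(dir, "treated.csv"),
             untreated = file.path(dir, "untreated.csv"))
  write_trajectory_csv(treated$measurements, paths[["treated"]])
  write_trajectory_csv(untreated$measurements, paths[["untreated"]])
  manifest <- list(model = model$kind,
                   params = model$params,
                   gompertz_form = model$gompertz_form,
                   alpha = alpha, seed = seed, v0_mm3 = v0_mm3,
                   dose_times = treated$doses,
                   kappa = kill_fraction, sigma = sigma)
  manifest_path <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = 12,
                              null = "null", pretty = TRUE),
             manifest_path)
  invisible(list(paths = paths, manifest_path = manifest_path,
                 manifest = manifest, treated = treated,
                 untreated = untreated))
}
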
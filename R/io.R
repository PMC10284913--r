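#' Read a tumor-volume measurement CSV
#'
#' Expects the package CSV dialect: header \code{time_days,volume_mm3},
#' comma-separated, '.' decimal point. Times must be strictly increasing
#' and volumes non-negative; violations are reported with the offending
#' line number (header = line 1).
#'
#' @param path file path.
#' @return a data.frame with columns \code{time_days}, \code{volume_mm3}.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("time_days", "volume_mm3")))
    stop(path, ": header must be 'time_days,volume_mm3'", call. = FALSE)
  bad <- which(!is.finite(df$time_days) | !is.finite(df$volume_mm3))
  if (length(bad))
    stop(path, ": malformed value at line ", bad[1] + 1L, call. = FALSE)
  neg <- which(df$volume_mm3 < 0)
  if (length(neg))
    stop(path, ": negative volume at line ", neg[1] + 1L, call. = FALSE)
  dec <- which(diff(df$time_days) <= 0)
  if (length(dec))
    stop(path, ": times not strictly increasing at line ", dec[1] + 2L,
         call. = FALSE)
  df
}

#' Write a measurement set in the package CSV dialect
#'
#' @param measurements data.frame with \code{time_days}, \code{volume_mm3}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_trajectory_csv <- function(measurements, path) {
  stopifnot(all(c("time_days", "volume_mm3") %in% names(measurements)))
  lines <- c("time_days,volume_mm3",
             sprintf("%s,%s",
                     formatC(measurements$time_days, format = "g",
                             digits = 15),
                     formatC(measurements$volume_mm3, format = "g",
                             digits = 15)))
  writeLines(lines, path)  # LF endings
  invisible(path)
}

#' Load and validate a pipeline run configuration
#'
#' Configurations may be a YAML file path or a list. Recognized keys:
#' \describe{
#'   \item{datasets}{named list of measurement CSV paths, or}
#'   \item{synthetic}{list with \code{seed} and optional generator
#'     arguments (\code{model}, \code{params}, \code{alpha},
#'     \code{v0_mm3}, \code{kappa}, \code{sigma}); fixture pair generated
#'     in \code{outdir}.}
#'   \item{models}{growth-law kinds to fit (non-empty).}
#'   \item{alpha_min, alpha_max, alpha_step}{fractional-order grid
#'     (defaults 0.7, 1.0, 0.01).}
#'   \item{grid_step}{resampling step in days (default 0.1).}
#'   \item{gompertz_form}{"with_v" or "without_v".}
#'   \item{unit_factor}{mm^3 per model volume unit (default 100).}
#'   \item{seed}{integer, drives all randomness (default 1).}
#'   \item{outdir}{output directory (default "fractumor-out").}
#'   \item{verbose}{logical (default TRUE).}
#' }
#' Unknown keys are rejected by name.
#'
#' @param config list or YAML file path.
#' @return validated configuration list of class \code{"run_config"}.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("datasets", "synthetic", "models", "alpha_min", "alpha_max",
             "alpha_step", "grid_step", "gompertz_form", "unit_factor",
             "seed", "outdir", "verbose")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults <- list(models = c("exponential", "logistic", "gompertz",
                              "bp_general", "bp_particular"),
                   alpha_min = 0.7, alpha_max = 1.0, alpha_step = 0.01,
                   grid_step = 0.1, gompertz_form = "with_v",
                   unit_factor = 100, seed = 1L,
                   outdir = "fractumor-out", verbose = TRUE)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$datasets) && is.null(cfg$synthetic))
    stop("config needs either 'datasets' or a 'synthetic' block",
         call. = FALSE)
  if (length(cfg$models) == 0)
    stop("config 'models' must list at least one growth-law kind",
         call. = FALSE)
  bad <- setdiff(cfg$models, c("exponential", "logistic", "gompertz",
                               "bp_general", "bp_particular"))
  if (length(bad))
    stop("unknown model kinds in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!(cfg$alpha_min > 0 && cfg$alpha_max <= 1 &&
        cfg$alpha_min < cfg$alpha_max && cfg$alpha_step > 0))
    stop("invalid alpha grid bounds in config", call. = FALSE)
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full identification pipeline
#'
#' For every dataset and growth-law kind: spline resampling, integer-order
#' Nelder-Mead fit, fractional-order sweep, well-posedness report; the
#' comparison table and per-model sweep curves are written to the output
#' directory as versioned JSON and plain CSV. Per-model failures are
#' isolated (recorded in the report); the run fails only if every fit
#' fails. Given a seed, the run is deterministic and the JSON report is
#' byte-stable.
#'
#' @param config a list, YAML path or [read_run_config()] result.
#' @return invisibly, a list with the \code{comparison} table (class
#'   \code{"growth_comparison"}), the per-fit \code{wellposedness} reports
#'   and the output file paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config)
  log_msg <- function(...) if (isTRUE(cfg$verbose)) message("[fractumor] ", ...)
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  set.seed(cfg$seed)

  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    gen_model <- if (is.null(syn$model)) growth_model("exponential", a = 0.109)
                 else do.call(growth_model, c(list(law = syn$model),
                                              syn$params))
    log_msg("generating synthetic fixture pair (seed ",
            syn$seed %||% cfg$seed, ")")
    fx <- make_fixture_pair(
      file.path(cfg$outdir, "fixtures"), seed = syn$seed %||% cfg$seed,
      model = gen_model, alpha = syn$alpha %||% 0.98,
      v0_mm3 = syn$v0_mm3 %||% 50, kill_fraction = syn$kappa %||% 0.4,
      sigma = syn$sigma %||% 0.05)
    dataset_paths <- fx$paths
  } else {
    dataset_paths <- unlist(cfg$datasets)
  }

  datasets <- lapply(dataset_paths, function(p)
    as_model_units(read_trajectory_csv(p), unit_factor = cfg$unit_factor))
  names(datasets) <- names(dataset_paths)

  log_msg("fitting ", length(cfg$models), " model kind(s) on ",
          length(datasets), " dataset(s)")
  alpha_grid <- seq(cfg$alpha_min, cfg$alpha_max, by = cfg$alpha_step)

  rows <- list()
  wps <- list()
  sweep_paths <- character(0)
  for (ds in names(datasets)) {
    for (kind in cfg$models) {
      fit <- tryCatch(
        fracfit(datasets[[ds]], kind = kind, alpha_grid = alpha_grid,
                grid_step = cfg$grid_step,
                gompertz_form = cfg$gompertz_form),
        error = function(e) e)
      if (inherits(fit, "error")) {
        log_msg("fit failed [", ds, " x ", kind, "]: ",
                conditionMessage(fit))
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = ds, model = kind, integer_mse = NA_real_,
          fractional_mse = NA_real_, fractional_alpha = NA_real_,
          ratio_percent = NA_real_, converged = FALSE,
          error = conditionMessage(fit))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds, model = kind,
        integer_mse = fit$integer$mse,
        fractional_mse = fit$fractional$mse,
        fractional_alpha = fit$fractional$alpha,
        ratio_percent = mse_reduction_percent(fit$integer$mse,
                                              fit$fractional$mse),
        converged = fit$integer$converged, error = NA_character_)
      log_msg(sprintf("%s x %s: integer MSE %.4g, fractional MSE %.4g at alpha %.2f",
                      ds, kind, fit$integer$mse, fit$fractional$mse,
                      fit$fractional$alpha))
      wps[[paste(ds, kind, sep = ".")]] <- wellposedness_report(
        fit$integer$model, alpha = fit$fractional$alpha,
        v_range = c(max(min(fit$resampled$volume), 1e-3),
                    max(max(fit$resampled$volume), 1)),
        t_bound = max(fit$resampled$time))
      sp <- file.path(cfg$outdir, sprintf("sweep_%s_%s.csv", ds, kind))
      utils::write.csv(as.data.frame(fit$sweep)[, c("alpha", "mse")], sp,
                       row.names = FALSE, quote = FALSE)
      sweep_paths <- c(sweep_paths, sp)
    }
  }
  comparison <- do.call(rbind, rows)
  rownames(comparison) <- NULL
  class(comparison) <- c("growth_comparison", "data.frame")
  if (all(!is.na(comparison$error)))
    stop("every fit failed; first error: ", comparison$error[1],
         call. = FALSE)

  report <- list(
    schema_version = "1.0",
    config = list(models = cfg$models, alpha_grid = range(alpha_grid),
                  alpha_step = cfg$alpha_step, grid_step = cfg$grid_step,
                  unit_factor = cfg$unit_factor, seed = cfg$seed),
    comparison = as.data.frame(comparison),
    wellposedness = lapply(wps, unclass))
  json_path <- file.path(cfg$outdir, "report.json")
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = 12,
                              null = "null", na = "null", pretty = TRUE),
             json_path)
  csv_path <- file.path(cfg$outdir, "comparison.csv")
  utils::write.csv(as.data.frame(comparison)[, c("model", "dataset",
                                                 "integer_mse",
                                                 "fractional_mse",
                                                 "fractional_alpha",
                                                 "ratio_percent")],
                   csv_path, row.names = FALSE, quote = FALSE)
  log_msg("report written to ", json_path)
  invisible(list(comparison = comparison, wellposedness = wps,
                 paths = c(report_json = json_path, comparison_csv = csv_path,
                           sweep_paths)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
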
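#' Read a temperature trace from CSV
#'
#' Expects the package's strict dialect: header `time_s,temp_C`,
#' comma-separated, "." decimal, UTF-8. Parse problems are reported
#' with the file name and offending row number.
#'
#' @param path Path to the CSV file.
#' @param label Trace label; defaults to the file name.
#' @return A [temperature_trace()].
#' @export
read_trace_csv <- function(path, label = basename(path)) {
  df <- read_strict_csv(path, c("time_s", "temp_C"))
  bad <- which(!is.finite(df$time_s) | !is.finite(df$temp_C))
  if (length(bad))
    stop(sprintf("%s: non-numeric value at data row %d", path, bad[1]),
         call. = FALSE)
  nondec <- which(diff(df$time_s) <= 0)
  if (length(nondec))
    stop(sprintf("%s: time not strictly increasing at data row %d",
                 path, nondec[1] + 1), call. = FALSE)
  temperature_trace(df$time_s, df$temp_C, label = label)
}

#' Write a temperature trace to CSV
#'
#' @param trace A [temperature_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "temperature_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read calibration points from CSV
#'
#' Expects header `conc_ug_per_mL,absorbance`.
#'
#' @param path Path to the CSV file.
#' @return A data frame suitable for [fit_calibration()].
#' @export
read_calibration_csv <- function(path) {
  df <- read_strict_csv(path, c("conc_ug_per_mL", "absorbance"))
  bad <- which(!is.finite(df$conc_ug_per_mL) | !is.finite(df$absorbance))
  if (length(bad))
    stop(sprintf("%s: non-numeric value at data row %d", path, bad[1]),
         call. = FALSE)
  df
}

# internal: strict CSV reader enforcing an exact header and numeric
# columns; values that fail to parse become NA for row-level reporting
read_strict_csv <- function(path, expected_header) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  if (!identical(trimws(header), expected_header))
    stop(sprintf("%s: expected header '%s', found '%s'", path,
                 paste(expected_header, collapse = ","),
                 paste(header, collapse = ",")), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0) return(stats::setNames(
    as.data.frame(matrix(numeric(0), ncol = length(expected_header))),
    expected_header))
  out <- as.data.frame(lapply(df, function(col)
    suppressWarnings(as.numeric(col))))
  names(out) <- expected_header
  out
}

#' Read and validate a run configuration
#'
#' One structured YAML file fully validated before any computation.
#' Recognized keys: `beam_area_cm2`, `power_density_W_per_cm2`,
#' `heat_capacity_total_J_per_K`, `absorbance`, `ambient_temp_C`,
#' `solvent_heat_W`, `theta_floor`, `plateau_k`, `loading_mode`,
#' `protocol` (list of segments with `start_s`, `end_s`, `power_W`),
#' and `paths` (free-form named list). Unknown keys are rejected.
#' The laser power in watts is `power_density_W_per_cm2 *
#' beam_area_cm2`; the beam area defaults to 1 cm^2.
#'
#' @param path Path to the YAML file.
#' @return An object of class `run_config`: the validated list plus a
#'   derived `laser_power_W` where the power density is given.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  allowed <- c("beam_area_cm2", "power_density_W_per_cm2",
               "heat_capacity_total_J_per_K", "absorbance",
               "ambient_temp_C", "solvent_heat_W", "theta_floor",
               "plateau_k", "loading_mode", "protocol", "paths")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (is.null(cfg$beam_area_cm2)) cfg$beam_area_cm2 <- 1
  positive <- c("beam_area_cm2", "power_density_W_per_cm2",
                "heat_capacity_total_J_per_K", "plateau_k")
  for (key in positive) {
    if (!is.null(cfg[[key]]) &&
        (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0))
      stop(sprintf("config key `%s` must be a positive number", key),
           call. = FALSE)
  }
  nonneg <- c("absorbance", "solvent_heat_W", "theta_floor")
  for (key in nonneg) {
    if (!is.null(cfg[[key]]) &&
        (!is.numeric(cfg[[key]]) || cfg[[key]] < 0))
      stop(sprintf("config key `%s` must be a non-negative number", key),
           call. = FALSE)
  }
  if (!is.null(cfg$loading_mode) &&
      !cfg$loading_mode %in% c("direct", "indirect"))
    stop("config key `loading_mode` must be 'direct' or 'indirect'",
         call. = FALSE)
  if (!is.null(cfg$protocol))
    cfg$protocol <- laser_protocol(cfg$protocol)
  if (!is.null(cfg$power_density_W_per_cm2))
    cfg$laser_power_W <- cfg$power_density_W_per_cm2 * cfg$beam_area_cm2
  structure(cfg, class = "run_config")
}

#' Render a result as a report table
#'
#' Flattens a pipeline result into a one- or many-row data frame at the
#' documented reporting precision (percentages to 1 decimal place, eta
#' to 3, tau to 0.1 s) and optionally writes it to CSV or
#' human-readable text.
#'
#' @param results An `efficiency_estimate`, `loading_result`,
#'   `stability_report`, or a data frame from the summary operations.
#' @param path Optional output path.
#' @param format `"csv"` or `"text"`; used when `path` is given.
#' @return The report data frame, invisibly when written to a file.
#' @export
write_report <- function(results, path = NULL,
                         format = c("csv", "text")) {
  format <- match.arg(format)
  df <- report_frame(results)
  if (is.null(path)) return(df)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(utils::capture.output(print(df, row.names = FALSE)),
               path)
  }
  invisible(df)
}

report_frame <- function(results) {
  if (inherits(results, "efficiency_estimate")) {
    data.frame(tau_s = round(results$tau_s, 1),
               hA_W_per_K = signif(results$hA, 4),
               eta = round(results$eta, 3),
               eta_percent = round(100 * results$eta, 1),
               dT_max_mix_K = round(results$dT_max_mix, 2),
               dT_max_h2o_K = round(results$dT_max_h2o, 2),
               r_squared = round(results$fit$r_squared, 4),
               n_points = results$fit$n_points,
               warnings = paste(results$warnings, collapse = "; "))
  } else if (inherits(results, "loading_result")) {
    data.frame(loaded_mg = round(results$loaded_mg, 4),
               dlc_percent = round(results$dlc_percent, 1),
               dle_percent = round(results$dle_percent, 1))
  } else if (inherits(results, "stability_report")) {
    cbind(results$cycles,
          peak_decay_K = round(results$peak_decay_K, 2))
  } else if (is.data.frame(results)) {
    results
  } else if (is.null(results) || length(results) == 0) {
    data.frame()
  } else {
    stop("unsupported result type for reporting", call. = FALSE)
  }
}
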
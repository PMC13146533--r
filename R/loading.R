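#' Fit a linear absorbance-concentration calibration curve
#'
#' Ordinary least squares of absorbance on concentration (Beer-Lambert
#' in the linear range): `absorbance = slope * conc + intercept`. An
#' intercept is included by default because instrument baselines are
#' real; `through_origin = TRUE` forces the ideal zero-blank line.
#'
#' @param points Data frame with columns `conc_ug_per_mL` and
#'   `absorbance`; at least 3 points over at least 2 distinct
#'   concentrations.
#' @param through_origin Logical; fit without intercept.
#' @return An object of class `calibration_curve`: list with `slope`
#'   (absorbance per ug/mL), `intercept`, `r_squared` and `valid_range`
#'   (observed concentration range, ug/mL).
#' @export
fit_calibration <- function(points, through_origin = FALSE) {
  if (!is.data.frame(points) ||
      !all(c("conc_ug_per_mL", "absorbance") %in% names(points)))
    stop("`points` needs columns conc_ug_per_mL and absorbance",
         call. = FALSE)
  conc <- points$conc_ug_per_mL
  abs_ <- points$absorbance
  if (length(conc) < 3)
    stop("degenerate fit: need at least 3 calibration points",
         call. = FALSE)
  if (length(unique(conc)) < 2 || stats::var(conc) == 0)
    stop("degenerate fit: no variance in concentration", call. = FALSE)
  fit <- if (through_origin) stats::lm(abs_ ~ conc - 1)
         else stats::lm(abs_ ~ conc)
  co <- stats::coef(fit)
  slope <- unname(co[["conc"]])
  if (!is.finite(slope) || slope <= 0)
    stop("invalid curve: calibration slope must be positive",
         call. = FALSE)
  # exact calibration lines are legitimate input; silence summary.lm's
  # perfect-fit warning
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = slope,
                 intercept = if (through_origin) 0 else unname(co[[1]]),
                 r_squared = r2,
                 valid_range = range(conc)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration: A = %.4g * c + %.4g (r^2 = %.4f, valid %g..%g ug/mL)\n",
              x$slope, x$intercept, x$r_squared,
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Concentration from a measured absorbance
#'
#' Inverts the calibration line:
#' `c = dilution_factor * (A - intercept) / slope`. Negative implied
#' concentrations are clamped to 0 with a warning; values outside the
#' calibrated range are returned with an out-of-range warning.
#'
#' @param curve A [fit_calibration()] result.
#' @param absorbance Measured absorbance (after dilution).
#' @param dilution_factor Dilution factor >= 1 applied before the
#'   measurement; default 1.
#' @return Concentration in ug/mL.
#' @export
concentration_from_absorbance <- function(curve, absorbance,
                                          dilution_factor = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  stop_if_not_scalar(absorbance, "absorbance")
  stop_if_not_scalar(dilution_factor, "dilution_factor")
  if (curve$slope <= 0)
    stop("invalid curve: non-positive slope", call. = FALSE)
  if (dilution_factor < 1)
    stop("`dilution_factor` must be >= 1", call. = FALSE)
  c_diluted <- (absorbance - curve$intercept) / curve$slope
  if (c_diluted < curve$valid_range[1] ||
      c_diluted > curve$valid_range[2])
    warning(sprintf(
      "implied concentration %.4g ug/mL outside calibrated range %g..%g",
      c_diluted, curve$valid_range[1], curve$valid_range[2]),
      call. = FALSE)
  conc <- dilution_factor * c_diluted
  if (conc < 0) {
    warning("negative implied concentration clamped to 0", call. = FALSE)
    conc <- 0
  }
  conc
}

#' Dye loading efficiency (DLE)
#'
#' Loaded dye mass as a percentage of the fed dye mass:
#' `DLE = 100 * loaded / fed`.
#'
#' @param loaded_mg Loaded dye mass in mg, 0 <= loaded <= fed.
#' @param fed_mg Fed dye mass in mg, > 0.
#' @return DLE in percent.
#' @examples
#' compute_dle(0.66, 1.0)  # 66
#' @export
compute_dle <- function(loaded_mg, fed_mg) {
  stop_if_not_scalar(loaded_mg, "loaded_mg")
  stop_if_not_scalar(fed_mg, "fed_mg")
  if (fed_mg <= 0) stop("`fed_mg` must be > 0", call. = FALSE)
  if (loaded_mg < 0) stop("`loaded_mg` must be >= 0", call. = FALSE)
  if (loaded_mg > fed_mg)
    stop("mass balance violated: loaded mass exceeds fed mass",
         call. = FALSE)
  100 * loaded_mg / fed_mg
}

#' Dye loading content (DLC)
#'
#' Loaded dye mass as a percentage of the mass of the dye-loaded
#' particles (carrier plus loaded dye):
#' `DLC = 100 * loaded / (carrier + loaded)`.
#'
#' @param loaded_mg Loaded dye mass in mg, >= 0.
#' @param carrier_mg Carrier (unloaded nanoparticle) mass in mg, > 0.
#' @return DLC in percent, strictly below 100.
#' @examples
#' compute_dlc(0.66, 1.0)  # 39.76 -> 39.8 at 1 d.p.
#' compute_dlc(0.46, 1.0)  # 31.51 -> 31.5 at 1 d.p.
#' @export
compute_dlc <- function(loaded_mg, carrier_mg) {
  stop_if_not_scalar(loaded_mg, "loaded_mg")
  stop_if_not_scalar(carrier_mg, "carrier_mg")
  if (carrier_mg <= 0) stop("`carrier_mg` must be > 0", call. = FALSE)
  if (loaded_mg < 0) stop("`loaded_mg` must be >= 0", call. = FALSE)
  100 * loaded_mg / (carrier_mg + loaded_mg)
}

#' Describe one loading experiment
#'
#' @param fed_dye_mg Fed dye mass in mg, > 0.
#' @param carrier_mg Carrier mass in mg, > 0.
#' @param measured_absorbance Measured absorbance of the assayed
#'   solution.
#' @param volume_mL Volume of the assayed solution in mL, > 0.
#' @param mode `"indirect"` (absorbance of the unloaded supernatant;
#'   loaded = fed - supernatant dye) or `"direct"` (absorbance of the
#'   loaded particles; loaded = measured dye).
#' @param dilution_factor Dilution applied before the measurement
#'   (at least 1).
#' @return An object of class `loading_experiment`.
#' @export
loading_experiment <- function(fed_dye_mg, carrier_mg,
                               measured_absorbance, volume_mL,
                               mode = c("indirect", "direct"),
                               dilution_factor = 1) {
  mode <- match.arg(mode)
  stop_if_not_scalar(fed_dye_mg, "fed_dye_mg")
  stop_if_not_scalar(carrier_mg, "carrier_mg")
  stop_if_not_scalar(measured_absorbance, "measured_absorbance")
  stop_if_not_scalar(volume_mL, "volume_mL")
  stop_if_not_scalar(dilution_factor, "dilution_factor")
  if (fed_dye_mg <= 0 || carrier_mg <= 0 || volume_mL <= 0)
    stop("masses and volume must be > 0", call. = FALSE)
  if (dilution_factor < 1)
    stop("`dilution_factor` must be >= 1", call. = FALSE)
  structure(list(fed_dye_mg = fed_dye_mg, carrier_mg = carrier_mg,
                 measured_absorbance = measured_absorbance,
                 volume_mL = volume_mL, mode = mode,
                 dilution_factor = dilution_factor),
            class = "loading_experiment")
}

#' Quantify dye loading from an absorbance measurement
#'
#' Converts the measured absorbance to a dye concentration via the
#' calibration curve, then to a loaded mass according to the
#' measurement mode, and reports DLE and DLC. In indirect mode the
#' loaded mass is fed mass minus the dye found in the supernatant; in
#' direct mode it is the dye measured on the particles themselves.
#' A negative computed loaded mass is clamped to 0 with a mass-balance
#' warning; a loaded mass exceeding the fed mass is an error.
#'
#' @param exp A [loading_experiment()].
#' @param curve A [fit_calibration()] result.
#' @return An object of class `loading_result`: list with `loaded_mg`,
#'   `dlc_percent`, `dle_percent`, plus the experiment for reference.
#' @export
quantify_loading <- function(exp, curve) {
  stopifnot(inherits(exp, "loading_experiment"),
            inherits(curve, "calibration_curve"))
  conc <- concentration_from_absorbance(curve, exp$measured_absorbance,
                                        exp$dilution_factor)
  measured_mg <- conc * exp$volume_mL / 1000  # ug/mL * mL -> ug -> mg
  loaded <- if (exp$mode == "indirect") exp$fed_dye_mg - measured_mg
            else measured_mg
  if (loaded < 0) {
    warning("mass balance: computed loaded mass below 0, clamped",
            call. = FALSE)
    loaded <- 0
  }
  if (loaded > exp$fed_dye_mg)
    stop("mass balance violated: loaded mass exceeds fed mass",
         call. = FALSE)
  structure(list(loaded_mg = loaded,
                 dlc_percent = compute_dlc(loaded, exp$carrier_mg),
                 dle_percent = compute_dle(loaded, exp$fed_dye_mg),
                 experiment = exp),
            class = "loading_result")
}

#' @export
print.loading_result <- function(x, ...) {
  cat(sprintf("Loading: %.3f mg loaded   DLC = %.1f%%   DLE = %.1f%%\n",
              x$loaded_mg, x$dlc_percent, x$dle_percent))
  invisible(x)
}
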
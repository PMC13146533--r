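#' Extract the cooling segment of a trace
#'
#' Slices the samples at or after laser shut-off and re-zeroes their
#' times at the shut-off instant, producing the cooling record that the
#' time-constant regression consumes.
#'
#' @param trace A [temperature_trace()].
#' @param laser_off_s Laser shut-off time in seconds; must lie within
#'   the trace span with at least 3 samples at or after it.
#' @return A [temperature_trace()] with times re-zeroed at laser-off.
#' @export
extract_cooling <- function(trace, laser_off_s) {
  stopifnot(inherits(trace, "temperature_trace"))
  stop_if_not_scalar(laser_off_s, "laser_off_s")
  keep <- trace$times >= laser_off_s
  if (sum(keep) < 3)
    stop("insufficient data: need at least 3 samples at or after laser-off",
         call. = FALSE)
  temperature_trace(trace$times[keep] - laser_off_s, trace$temps[keep],
                    label = paste0(trace$label, " [cooling]"))
}

#' Dimensionless cooling temperature series
#'
#' Converts a cooling trace to the driving-force ratio
#' \eqn{\theta_i = (T_i - T_{surr}) / (T_{max} - T_{surr})}, the
#' quantity whose logarithm is linear in time during Newtonian cooling.
#' Points with \eqn{\theta \le} `theta_floor` (too close to ambient:
#' the variance of \eqn{-\ln\theta} explodes there) or \eqn{\theta > 1}
#' (above the stated maximum, e.g. the overshoot sample right at
#' shut-off) are dropped and counted.
#'
#' @param cooling A [temperature_trace()] with times measured from
#'   laser-off.
#' @param ambient_temp Ambient temperature in deg C.
#' @param max_temp Maximum steady-state temperature in deg C; must
#'   exceed `ambient_temp`.
#' @param theta_floor Retention floor for theta; default 0.05.
#' @return An object of class `theta_series`: list with `times`,
#'   `theta`, `theta_floor`, `n_dropped_low`, `n_dropped_high`.
#' @export
compute_theta <- function(cooling, ambient_temp, max_temp,
                          theta_floor = 0.05) {
  stopifnot(inherits(cooling, "temperature_trace"))
  stop_if_not_scalar(ambient_temp, "ambient_temp")
  stop_if_not_scalar(max_temp, "max_temp")
  if (max_temp <= ambient_temp)
    stop("`max_temp` must exceed `ambient_temp`", call. = FALSE)
  theta <- (cooling$temps - ambient_temp) / (max_temp - ambient_temp)
  low <- theta <= theta_floor
  high <- theta > 1
  keep <- !low & !high
  if (!any(keep))
    stop("insufficient data: all theta points dropped", call. = FALSE)
  structure(list(times = cooling$times[keep], theta = theta[keep],
                 theta_floor = theta_floor,
                 n_dropped_low = sum(low), n_dropped_high = sum(high)),
            class = "theta_series")
}

#' @export
print.theta_series <- function(x, ...) {
  cat(sprintf("Theta series: %d points retained (%d below floor %.3g, %d above 1)\n",
              length(x$theta), x$n_dropped_low, x$theta_floor,
              x$n_dropped_high))
  invisible(x)
}

#' Fit the cooling time constant
#'
#' Ordinary least squares of time against \eqn{-\ln\theta}; during
#' Newtonian cooling \eqn{t = \tau \cdot (-\ln\theta)}, so the slope is
#' the time constant \eqn{\tau = \sum m C_p / hA}. By default an
#' intercept is included (it absorbs any offset in the laser-off
#' timing); `through_origin = TRUE` forces the theoretical
#' zero-intercept line.
#'
#' @param series A `theta_series` from [compute_theta()].
#' @param through_origin Logical; fit without intercept. Default FALSE.
#' @return An object of class `time_constant_fit`: list with `tau_s`,
#'   `intercept_s`, `r_squared`, `n_points`, `theta_floor`.
#' @export
fit_time_constant <- function(series, through_origin = FALSE) {
  stopifnot(inherits(series, "theta_series"))
  if (length(series$theta) < 3)
    stop("insufficient data: need at least 3 retained theta points",
         call. = FALSE)
  x <- -log(series$theta)
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0)
    stop("degenerate fit: no variance in -ln(theta)", call. = FALSE)
  fit <- if (through_origin) stats::lm(series$times ~ x - 1)
         else stats::lm(series$times ~ x)
  co <- stats::coef(fit)
  tau <- unname(co[["x"]])
  if (!is.finite(tau) || tau <= 0)
    stop("degenerate fit: non-positive time constant", call. = FALSE)
  # summary.lm warns on noiseless input ("essentially perfect fit");
  # a perfect fit is an expected case here, not a problem
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(tau_s = tau,
                 intercept_s = if (through_origin) 0
                               else unname(co[[1]]),
                 r_squared = r2,
                 n_points = length(x),
                 theta_floor = series$theta_floor),
            class = "time_constant_fit")
}

#' @export
print.time_constant_fit <- function(x, ...) {
  cat(sprintf("Time-constant fit: tau = %.1f s (intercept %.1f s, r^2 = %.4f, n = %d)\n",
              x$tau_s, x$intercept_s, x$r_squared, x$n_points))
  invisible(x)
}

#' Heat-transfer product from the time constant
#'
#' Rearranges \eqn{\tau = \sum m C_p / hA} to
#' \eqn{hA = \sum m C_p / \tau}.
#'
#' @param tau_s Time constant in seconds, > 0.
#' @param heat_capacity_total Total heat capacity in J/K, > 0.
#' @return hA in W/K.
#' @examples
#' compute_hA(300, 4.2)  # 0.014 W/K
#' @export
compute_hA <- function(tau_s, heat_capacity_total) {
  stop_if_not_scalar(tau_s, "tau_s")
  stop_if_not_scalar(heat_capacity_total, "heat_capacity_total")
  if (tau_s <= 0 || heat_capacity_total <= 0)
    stop("`tau_s` and `heat_capacity_total` must be > 0", call. = FALSE)
  heat_capacity_total / tau_s
}

#' Photothermal conversion efficiency
#'
#' The steady-state energy balance gives
#' \deqn{\eta = \frac{hA\,(\Delta T_{max,mix} - \Delta T_{max,H_2O})}
#'                   {I\,(1 - 10^{-A})},}
#' where \eqn{\Delta T_{max,mix}} and \eqn{\Delta T_{max,H_2O}} are the
#' maximum steady-state rises of the sample suspension and of the pure
#' solvent under identical irradiation, \eqn{I} the laser power and
#' \eqn{A} the sample absorbance at the laser wavelength. Values outside
#' \[0, 1\] are returned with a warning rather than rejected:
#' measurement noise can push estimates past the physical bounds.
#'
#' @param hA Heat-transfer product in W/K, > 0.
#' @param dT_max_mix Steady-state rise of the sample in K.
#' @param dT_max_h2o Steady-state rise of the solvent reference in K.
#' @param laser_power Laser power I in W, > 0.
#' @param absorbance Sample absorbance at the laser wavelength, > 0.
#' @return Efficiency eta (dimensionless).
#' @examples
#' compute_eta(0.015, 35.7, 0.5, 1.2, 1.0)  # 0.4889
#' @export
compute_eta <- function(hA, dT_max_mix, dT_max_h2o, laser_power,
                        absorbance) {
  stop_if_not_scalar(hA, "hA")
  stop_if_not_scalar(dT_max_mix, "dT_max_mix")
  stop_if_not_scalar(dT_max_h2o, "dT_max_h2o")
  stop_if_not_scalar(laser_power, "laser_power")
  stop_if_not_scalar(absorbance, "absorbance")
  if (hA <= 0) stop("`hA` must be > 0", call. = FALSE)
  if (laser_power <= 0) stop("`laser_power` must be > 0", call. = FALSE)
  if (absorbance <= 0)
    stop("`absorbance` must be > 0: 1 - 10^(-A) vanishes at A = 0",
         call. = FALSE)
  if (dT_max_h2o < 0 || dT_max_mix < dT_max_h2o)
    stop("need dT_max_mix >= dT_max_h2o >= 0", call. = FALSE)
  eta <- hA * (dT_max_mix - dT_max_h2o) /
    (laser_power * (1 - 10^(-absorbance)))
  if (eta > 1)
    warning(sprintf("estimated eta = %.3f exceeds 1; flagged, not rejected",
                    eta), call. = FALSE)
  eta
}

#' Estimate the photothermal conversion efficiency from traces
#'
#' Runs the whole cooling-curve inference: takes the plateau temperature
#' rise of the sample and of the solvent reference, extracts the
#' sample's cooling segment, linearizes it via \eqn{-\ln\theta}, fits
#' the time constant, converts it to \eqn{hA}, and evaluates the
#' efficiency.
#'
#' The plateau rise is the mean of the last `plateau_k` samples of the
#' laser-on window minus ambient (a single-sample maximum is
#' noise-biased); when fewer than `plateau_k` on-window samples exist
#' the maximum temperature is used with a warning.
#'
#' @param sample_trace [temperature_trace()] of the photothermal sample.
#' @param water_trace [temperature_trace()] of the solvent reference
#'   measured under the identical protocol.
#' @param laser_off_s Laser shut-off time in seconds.
#' @param heat_capacity_total Total heat capacity in J/K.
#' @param laser_power Laser power in W.
#' @param absorbance Sample absorbance at the laser wavelength.
#' @param ambient_temp Ambient temperature in deg C (from the run
#'   configuration, not the trace tail: a 10-min cooling window need
#'   not reach ambient).
#' @param theta_floor Theta retention floor; see [compute_theta()].
#' @param plateau_k Number of trailing on-window samples averaged for
#'   the plateau; default 3.
#' @param through_origin Force the time-constant regression through the
#'   origin; default FALSE.
#' @return An object of class `efficiency_estimate`: list with `tau_s`,
#'   `hA`, `eta`, `dT_max_mix`, `dT_max_h2o`, `laser_power`,
#'   `absorbance`, `fit` (a `time_constant_fit`) and `warnings`
#'   (character vector of flags, e.g. eta outside \[0, 1\]).
#' @export
estimate_efficiency <- function(sample_trace, water_trace, laser_off_s,
                                heat_capacity_total, laser_power,
                                absorbance, ambient_temp,
                                theta_floor = 0.05, plateau_k = 3,
                                through_origin = FALSE) {
  stopifnot(inherits(sample_trace, "temperature_trace"),
            inherits(water_trace, "temperature_trace"))
  warnings <- character(0)
  plat <- function(trace, what) {
    on_idx <- which(trace$times <= laser_off_s)
    if (length(on_idx) == 0)
      stop(sprintf("no %s samples in the laser-on window", what),
           call. = FALSE)
    if (length(on_idx) < plateau_k) {
      warnings <<- c(warnings, sprintf(
        "%s: fewer than %d on-window samples; using max temperature",
        what, plateau_k))
      max(trace$temps[on_idx])
    } else {
      mean(trace$temps[utils::tail(on_idx, plateau_k)])
    }
  }
  plateau_mix <- plat(sample_trace, "sample")
  plateau_h2o <- plat(water_trace, "water")
  dT_mix <- plateau_mix - ambient_temp
  dT_h2o <- plateau_h2o - ambient_temp
  if (dT_h2o < 0) {
    # a solvent reference can only be heated; a negative measured rise
    # is measurement noise around zero
    warnings <- c(warnings,
                  "water plateau rise below 0; clamped to 0")
    dT_h2o <- 0
  }
  cooling <- extract_cooling(sample_trace, laser_off_s)
  theta <- compute_theta(cooling, ambient_temp, plateau_mix,
                         theta_floor = theta_floor)
  fit <- fit_time_constant(theta, through_origin = through_origin)
  hA <- compute_hA(fit$tau_s, heat_capacity_total)
  eta <- withCallingHandlers(
    compute_eta(hA, dT_mix, dT_h2o, laser_power, absorbance),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (eta < 0) warnings <- c(warnings, "estimated eta below 0; flagged")
  structure(list(tau_s = fit$tau_s, hA = hA, eta = eta,
                 dT_max_mix = dT_mix, dT_max_h2o = dT_h2o,
                 laser_power = laser_power, absorbance = absorbance,
                 fit = fit, warnings = warnings),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat("Photothermal efficiency estimate\n")
  cat(sprintf("  tau: %.1f s   hA: %.4g W/K   eta: %.3f (%.1f%%)\n",
              x$tau_s, x$hA, x$eta, 100 * x$eta))
  cat(sprintf("  dT_max sample: %.2f K   dT_max solvent: %.2f K\n",
              x$dT_max_mix, x$dT_max_h2o))
  cat(sprintf("  regression: r^2 = %.4f on %d points (theta floor %.3g)\n",
              x$fit$r_squared, x$fit$n_points, x$fit$theta_floor))
  if (length(x$warnings))
    cat("  flags:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
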
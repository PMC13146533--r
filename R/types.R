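#' Construct a thermal system description
#'
#' Bundles the physical parameters of one cuvette experiment under the
#' lumped-capacitance energy balance: the total heat capacity
#' \eqn{\sum_i m_i C_{p,i}} of solvent plus container, the heat-transfer
#' product \eqn{hA} (heat-transfer coefficient times container surface
#' area), the photothermal conversion efficiency \eqn{\eta}, the sample
#' absorbance at the laser wavelength, the solvent heating power
#' \eqn{Q_s}, and the ambient temperature. Only the product \eqn{hA} is
#' modelled; \eqn{h} and \eqn{A} are not separately identifiable from a
#' single cooling curve.
#'
#' @param heat_capacity_total Total heat capacity in J/K; must be positive.
#' @param hA Heat-transfer product in W/K; must be positive.
#' @param eta Photothermal conversion efficiency, dimensionless in
#'   \[0, 1\].
#' @param absorbance Absorbance of the sample at the laser wavelength
#'   (typically 808 nm), dimensionless, non-negative.
#' @param solvent_heat Heat absorbed by the solvent per second while the
#'   laser is on, in W; non-negative. Defaults to 0.
#' @param ambient_temp Ambient (surrounding) temperature in deg C.
#'
#' @return An object of class `thermal_system`: a list with the fields
#'   above plus `tau_s`, the relaxation time constant
#'   `heat_capacity_total / hA` in seconds.
#'
#' @examples
#' sys <- thermal_system(heat_capacity_total = 4.2, hA = 0.014,
#'                       eta = 0.76, absorbance = 0.65,
#'                       solvent_heat = 0.007, ambient_temp = 26.3)
#' sys$tau_s  # 300 s
#' @export
thermal_system <- function(heat_capacity_total, hA, eta, absorbance,
                           solvent_heat = 0, ambient_temp = 25) {
  stop_if_not_scalar(heat_capacity_total, "heat_capacity_total")
  stop_if_not_scalar(hA, "hA")
  stop_if_not_scalar(eta, "eta")
  stop_if_not_scalar(absorbance, "absorbance")
  stop_if_not_scalar(solvent_heat, "solvent_heat")
  stop_if_not_scalar(ambient_temp, "ambient_temp")
  if (heat_capacity_total <= 0)
    stop("`heat_capacity_total` must be > 0 (J/K)", call. = FALSE)
  if (hA <= 0)
    stop("`hA` must be > 0 (W/K)", call. = FALSE)
  if (eta < 0 || eta > 1)
    stop("`eta` must lie in [0, 1]", call. = FALSE)
  if (absorbance < 0)
    stop("`absorbance` must be >= 0", call. = FALSE)
  if (solvent_heat < 0)
    stop("`solvent_heat` must be >= 0 (W)", call. = FALSE)
  structure(
    list(heat_capacity_total = heat_capacity_total,
         hA = hA,
         eta = eta,
         absorbance = absorbance,
         solvent_heat = solvent_heat,
         ambient_temp = ambient_temp,
         tau_s = heat_capacity_total / hA),
    class = "thermal_system")
}

#' @export
print.thermal_system <- function(x, ...) {
  cat("Thermal system (lumped-capacitance)\n")
  cat(sprintf("  heat capacity: %.4g J/K   hA: %.4g W/K   tau: %.1f s\n",
              x$heat_capacity_total, x$hA, x$tau_s))
  cat(sprintf("  eta: %.3f   absorbance: %.3f   Q_s: %.4g W   ambient: %.1f degC\n",
              x$eta, x$absorbance, x$solvent_heat, x$ambient_temp))
  invisible(x)
}

#' Construct a laser on/off protocol
#'
#' An ordered sequence of constant-power laser segments. Power 0 encodes
#' laser-off; gaps between segments are treated as laser-off when
#' simulating.
#'
#' @param segments A data frame with columns `start_s`, `end_s`,
#'   `power_W` (one row per segment), or a list of 3-element lists/
#'   vectors in that order. Segments must be sorted by `start_s`,
#'   non-overlapping, with `start_s < end_s` and `power_W >= 0`.
#'
#' @return An object of class `laser_protocol` wrapping the validated
#'   segment table.
#'
#' @examples
#' # 10 min on at 2.5 W, 10 min natural cooling, four cycles
#' prot <- cycled_protocol(power_W = 2.5, on_s = 600, off_s = 600,
#'                         n_cycles = 4)
#' prot
#' @export
laser_protocol <- function(segments) {
  if (is.list(segments) && !is.data.frame(segments)) {
    segments <- do.call(rbind, lapply(segments, function(s) {
      s <- unlist(s)
      data.frame(start_s = s[["start_s"]], end_s = s[["end_s"]],
                 power_W = s[["power_W"]])
    }))
  }
  if (!is.data.frame(segments) ||
      !all(c("start_s", "end_s", "power_W") %in% names(segments)))
    stop("`segments` needs columns start_s, end_s, power_W", call. = FALSE)
  segments <- segments[, c("start_s", "end_s", "power_W")]
  if (nrow(segments) < 1)
    stop("protocol needs at least one segment", call. = FALSE)
  if (!all(vapply(segments, is.numeric, logical(1))) ||
      anyNA(segments) || any(!is.finite(as.matrix(segments))))
    stop("protocol segments must be finite numbers", call. = FALSE)
  if (any(segments$start_s >= segments$end_s))
    stop("each segment needs start_s < end_s", call. = FALSE)
  if (any(segments$power_W < 0))
    stop("segment power_W must be >= 0", call. = FALSE)
  if (is.unsorted(segments$start_s, strictly = TRUE))
    stop("segments must be sorted by start_s", call. = FALSE)
  if (nrow(segments) > 1 &&
      any(segments$end_s[-nrow(segments)] > segments$start_s[-1]))
    stop("segments must not overlap", call. = FALSE)
  structure(list(segments = segments), class = "laser_protocol")
}

#' @rdname laser_protocol
#' @param power_W Laser power in W during the on phase.
#' @param on_s Duration of each laser-on phase in seconds.
#' @param off_s Duration of each laser-off phase in seconds.
#' @param n_cycles Number of on/off cycles.
#' @param start_s Start time of the first cycle in seconds.
#' @export
cycled_protocol <- function(power_W, on_s = 600, off_s = 600,
                            n_cycles = 1, start_s = 0) {
  starts <- start_s + (seq_len(n_cycles) - 1) * (on_s + off_s)
  segs <- data.frame(
    start_s = as.vector(rbind(starts, starts + on_s)),
    end_s   = as.vector(rbind(starts + on_s, starts + on_s + off_s)),
    power_W = rep(c(power_W, 0), n_cycles))
  laser_protocol(segs)
}

#' @export
print.laser_protocol <- function(x, ...) {
  n <- nrow(x$segments)
  cat(sprintf("Laser protocol: %d segment%s, %g..%g s\n", n,
              if (n == 1) "" else "s",
              min(x$segments$start_s), max(x$segments$end_s)))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Construct a sampled temperature trace
#'
#' The universal measurement record: a series of (time, temperature)
#' samples as logged by a thermal imager.
#'
#' @param times Sample times in seconds; strictly increasing, length >= 2.
#' @param temps Temperatures in deg C, same length as `times`, finite.
#' @param label Free-text label carried through reports.
#'
#' @return An object of class `temperature_trace`: a list with `times`,
#'   `temps` and `label`.
#' @export
temperature_trace <- function(times, temps, label = "") {
  if (!is.numeric(times) || !is.numeric(temps))
    stop("`times` and `temps` must be numeric", call. = FALSE)
  if (length(times) != length(temps))
    stop("`times` and `temps` must have equal length", call. = FALSE)
  if (length(times) < 2)
    stop("a trace needs at least 2 samples", call. = FALSE)
  if (anyNA(times) || any(!is.finite(times)) ||
      anyNA(temps) || any(!is.finite(temps)))
    stop("trace values must be finite", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times), temps = as.numeric(temps),
                 label = as.character(label)[1]),
            class = "temperature_trace")
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf("Temperature trace%s: %d samples, t = %g..%g s, T = %.2f..%.2f degC\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$times), min(x$times), max(x$times),
              min(x$temps), max(x$temps)))
  invisible(x)
}

#' @export
as.data.frame.temperature_trace <- function(x, ...) {
  data.frame(time_s = x$times, temp_C = x$temps)
}

# internal: scalar-finite argument guard
stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name),
         call. = FALSE)
  invisible(TRUE)
}
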
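#' Heat input power of an irradiated sample
#'
#' Evaluates the energy-balance source term: the heat generated by the
#' photothermal agent, \eqn{Q_{NPs} = I (1 - 10^{-A}) \eta}, plus the
#' solvent heating term \eqn{Q_s}. `I` is the laser power in W, `A` the
#' sample absorbance at the laser wavelength and \eqn{\eta} the
#' photothermal conversion efficiency.
#'
#' With `laser_power = 0` the formula returns `solvent_heat` alone; note
#' that [simulate_trace()] gates the whole source term by laser on/off,
#' since the solvent term also represents absorbed light.
#'
#' @param system A [thermal_system()].
#' @param laser_power Laser power in W, >= 0.
#' @return Heat input in W.
#' @examples
#' sys <- thermal_system(4.2, 0.014, eta = 0.5, absorbance = 1,
#'                       solvent_heat = 0.01)
#' input_power(sys, 2)  # 2 * 0.9 * 0.5 + 0.01 = 0.91 W
#' @export
input_power <- function(system, laser_power) {
  stopifnot(inherits(system, "thermal_system"))
  stop_if_not_scalar(laser_power, "laser_power")
  if (laser_power < 0)
    stop("`laser_power` must be >= 0 (W)", call. = FALSE)
  laser_power * (1 - 10^(-system$absorbance)) * system$eta +
    system$solvent_heat
}

#' Steady-state temperature rise under constant irradiation
#'
#' At steady state the heat input equals the loss \eqn{hA \Delta T}, so
#' the maximum rise above ambient is
#' \eqn{\Delta T_{max} = (Q_{NPs} + Q_s) / hA}.
#'
#' @inheritParams input_power
#' @return Steady-state temperature rise in K.
#' @examples
#' sys <- thermal_system(4.2, 0.015, eta = 0.5, absorbance = 1)
#' steady_state_delta(sys, 1)  # 0.45 / 0.015 = 30 K
#' @export
steady_state_delta <- function(system, laser_power) {
  stopifnot(inherits(system, "thermal_system"))
  input_power(system, laser_power) / system$hA
}

#' Simulate a temperature trace under a laser protocol
#'
#' Noiseless solution of the lumped energy balance
#' \deqn{\sum_i m_i C_{p,i} \frac{dT}{dt} = Q(t) - hA (T - T_{surr}),}
#' where \eqn{Q(t)} is the (piecewise-constant) heat input of the active
#' protocol segment and zero while the laser is off. Because the balance
#' is linear in T on each constant-power segment, the solution is the
#' exact piecewise exponential: each segment relaxes toward
#' \eqn{T_{surr} + Q/hA} with time constant \eqn{\tau = \sum m C_p / hA},
#' continuous across segment boundaries. No numerical integration is
#' involved.
#'
#' Gaps between protocol segments and times after the last segment are
#' treated as laser-off. Sample times before the protocol start are not
#' allowed.
#'
#' @param system A [thermal_system()].
#' @param protocol A [laser_protocol()].
#' @param sample_times Times in seconds at which to evaluate the
#'   solution; must be non-empty, sorted strictly increasing, and at or
#'   after the protocol start.
#' @param init_temp Temperature at the protocol start, in deg C.
#'   Defaults to the system's ambient temperature.
#' @param label Label for the returned trace.
#' @return A [temperature_trace()].
#' @examples
#' sys <- thermal_system(4.2, 0.014, eta = 0.76, absorbance = 0.65,
#'                       ambient_temp = 26.3)
#' prot <- cycled_protocol(power_W = 2.5, on_s = 600, off_s = 600)
#' simulate_trace(sys, prot, seq(0, 1200, by = 60))
#' @export
simulate_trace <- function(system, protocol, sample_times,
                           init_temp = system$ambient_temp,
                           label = "simulated") {
  stopifnot(inherits(system, "thermal_system"),
            inherits(protocol, "laser_protocol"))
  if (length(sample_times) == 0)
    stop("`sample_times` must be non-empty", call. = FALSE)
  if (!is.numeric(sample_times) || anyNA(sample_times) ||
      any(!is.finite(sample_times)))
    stop("`sample_times` must be finite numbers", call. = FALSE)
  if (is.unsorted(sample_times, strictly = TRUE))
    stop("`sample_times` must be strictly increasing", call. = FALSE)
  segs <- protocol$segments
  t0 <- segs$start_s[1]
  if (min(sample_times) < t0)
    stop("`sample_times` must lie within or after the protocol span",
         call. = FALSE)
  horizon <- max(max(sample_times), max(segs$end_s))
  sched <- protocol_schedule(segs, t0, horizon)
  temps <- piecewise_exponential(
    sample_times, sched$start, sched$end,
    q_watts = vapply(sched$power, function(p)
      if (p > 0) input_power(system, p) else 0, numeric(1)),
    hA = system$hA, tau = system$tau_s,
    ambient = system$ambient_temp, init_temp = init_temp)
  temperature_trace(sample_times, temps, label = label)
}

#' Analytic cooling curve
#'
#' Newtonian cooling after laser shut-off: with the source term zero the
#' balance reduces to \eqn{T(t) = T_{surr} + (T_0 - T_{surr}) e^{-t/\tau}}
#' with \eqn{\tau = \sum m C_p / hA}.
#'
#' @param system A [thermal_system()].
#' @param start_temp Temperature at laser-off in deg C; must be at or
#'   above ambient.
#' @param times Times since laser-off in seconds, >= 0, strictly
#'   increasing.
#' @param label Label for the returned trace.
#' @return A [temperature_trace()].
#' @export
analytic_cooling <- function(system, start_temp, times,
                             label = "cooling") {
  stopifnot(inherits(system, "thermal_system"))
  stop_if_not_scalar(start_temp, "start_temp")
  if (start_temp < system$ambient_temp)
    stop("`start_temp` must be at or above ambient", call. = FALSE)
  if (any(times < 0))
    stop("`times` must be >= 0 (seconds since laser-off)", call. = FALSE)
  temps <- system$ambient_temp +
    (start_temp - system$ambient_temp) * exp(-times / system$tau_s)
  temperature_trace(times, temps, label = label)
}

# internal: expand protocol segments into a gap-free schedule of
# (start, end, power) pieces covering [t0, horizon], laser-off in gaps
protocol_schedule <- function(segs, t0, horizon) {
  start <- numeric(0); end <- numeric(0); power <- numeric(0)
  cur <- t0
  for (i in seq_len(nrow(segs))) {
    if (segs$start_s[i] > cur) {           # off-gap before this segment
      start <- c(start, cur); end <- c(end, segs$start_s[i])
      power <- c(power, 0)
    }
    start <- c(start, segs$start_s[i]); end <- c(end, segs$end_s[i])
    power <- c(power, segs$power_W[i])
    cur <- segs$end_s[i]
  }
  if (horizon > cur) {                      # trailing off period
    start <- c(start, cur); end <- c(end, horizon)
    power <- c(power, 0)
  }
  list(start = start, end = end, power = power)
}

# internal: exact piecewise-exponential evaluation. Each piece i has
# constant heat input q_watts[i]; the state relaxes toward
# ambient + q/hA with time constant tau, continuously across pieces.
piecewise_exponential <- function(times, start, end, q_watts, hA, tau,
                                  ambient, init_temp) {
  temps <- numeric(length(times))
  T_cur <- init_temp
  for (i in seq_along(start)) {
    T_inf <- ambient + q_watts[i] / hA
    # include right boundary on the last piece only; boundaries belong
    # to the piece that starts there so traces are continuous
    in_piece <- times >= start[i] &
      (if (i == length(start)) times <= end[i] else times < end[i])
    if (any(in_piece)) {
      dt <- times[in_piece] - start[i]
      temps[in_piece] <- T_inf + (T_cur - T_inf) * exp(-dt / tau)
    }
    T_cur <- T_inf + (T_cur - T_inf) * exp(-(end[i] - start[i]) / tau)
  }
  temps
}
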
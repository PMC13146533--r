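# shared fixtures: small thermal systems with known closed-form behavior

ref_system <- function(tau_s = 300, eta = 0.76, absorbance = 0.65,
                       solvent_heat = 0, ambient = 26.3,
                       heat_capacity = 4.2) {
  thermal_system(heat_capacity_total = heat_capacity,
                 hA = heat_capacity / tau_s, eta = eta,
                 absorbance = absorbance, solvent_heat = solvent_heat,
                 ambient_temp = ambient)
}

# numeric ODE integration of the same energy balance, used as an
# independent oracle for the piecewise-exponential solution; integrates
# piece by piece so the discontinuous source never crosses a step
ode_oracle <- function(system, protocol, sample_times,
                       init_temp = system$ambient_temp) {
  segs <- protocol$segments
  bounds <- sort(unique(c(segs$start_s, segs$end_s, max(sample_times))))
  bounds <- bounds[bounds >= segs$start_s[1]]
  q_of_piece <- function(lo) {
    i <- which(lo >= segs$start_s & lo < segs$end_s)
    if (length(i) == 1 && segs$power_W[i] > 0)
      input_power(system, segs$power_W[i])
    else 0
  }
  result <- rep(NA_real_, length(sample_times))
  T_cur <- init_temp
  for (j in seq_len(length(bounds) - 1)) {
    lo <- bounds[j]; hi <- bounds[j + 1]
    q <- q_of_piece(lo)
    inside <- which(sample_times >= lo & sample_times <= hi)
    times <- sort(unique(c(lo, sample_times[inside], hi)))
    deriv <- function(t, y, parms)
      list((q - system$hA * (y[1] - system$ambient_temp)) /
             system$heat_capacity_total)
    out <- deSolve::ode(y = c(T = T_cur), times = times, func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-11, atol = 1e-11)
    result[inside] <- out[match(sample_times[inside], out[, "time"]), 2]
    T_cur <- unname(out[nrow(out), 2])
  }
  # samples exactly at the first boundary
  at_start <- sample_times == bounds[1]
  result[at_start] <- init_temp
  result
}
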
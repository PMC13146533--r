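#' Specification for a synthetic temperature trace
#'
#' Describes one emulated thermal-imager run: the physical system, the
#' laser protocol, the sampling interval (default 60 s, the cadence of
#' a handheld thermal imager), the additive Gaussian measurement noise,
#' an optional per-cycle photobleaching decay of the conversion
#' efficiency, and the seed making the draw reproducible.
#'
#' @param system A [thermal_system()]; its `eta` is the first-cycle
#'   ground truth.
#' @param protocol A [laser_protocol()].
#' @param sampling_interval_s Sampling interval in seconds, > 0;
#'   default 60.
#' @param noise_sigma_K Standard deviation of the additive Gaussian
#'   temperature noise in K, >= 0; default 0.2 (typical thermal-imager
#'   precision).
#' @param bleaching_per_cycle Fractional reduction of eta per completed
#'   on/off cycle, in \[0, 1); default 0. Phenomenological: eta of
#'   laser-on segment k is `eta * (1 - bleaching)^(k-1)`.
#' @param seed Integer seed.
#' @return An object of class `trace_gen_spec`.
#' @export
trace_gen_spec <- function(system, protocol, sampling_interval_s = 60,
                           noise_sigma_K = 0.2,
                           bleaching_per_cycle = 0, seed = 1L) {
  stopifnot(inherits(system, "thermal_system"),
            inherits(protocol, "laser_protocol"))
  stop_if_not_scalar(sampling_interval_s, "sampling_interval_s")
  stop_if_not_scalar(noise_sigma_K, "noise_sigma_K")
  stop_if_not_scalar(bleaching_per_cycle, "bleaching_per_cycle")
  if (sampling_interval_s <= 0)
    stop("`sampling_interval_s` must be > 0", call. = FALSE)
  if (noise_sigma_K < 0)
    stop("`noise_sigma_K` must be >= 0", call. = FALSE)
  if (bleaching_per_cycle < 0 || bleaching_per_cycle >= 1)
    stop("`bleaching_per_cycle` must lie in [0, 1)", call. = FALSE)
  structure(list(system = system, protocol = protocol,
                 sampling_interval_s = sampling_interval_s,
                 noise_sigma_K = noise_sigma_K,
                 bleaching_per_cycle = bleaching_per_cycle,
                 seed = as.integer(seed)),
            class = "trace_gen_spec")
}

#' Generate a synthetic temperature trace with ground truth
#'
#' Evaluates the exact piecewise-exponential forward model (with eta
#' geometrically reduced per completed cycle when bleaching is
#' requested) at the spec's sampling grid, then adds independent
#' Gaussian noise. Identical specs (including seed) give identical
#' output; the RNG state of the session is left untouched.
#'
#' @param spec A [trace_gen_spec()].
#' @param init_temp Starting temperature in deg C; defaults to ambient.
#' @param label Trace label.
#' @return A list with members `trace` (the noisy
#'   [temperature_trace()]), `noiseless` (the model evaluation) and
#'   `truth` (list: `tau_s`, `hA`, `eta_per_cycle`,
#'   `dT_max_per_cycle` in K at the protocol's on-power).
#' @export
make_trace <- function(spec, init_temp = spec$system$ambient_temp,
                       label = "synthetic") {
  stopifnot(inherits(spec, "trace_gen_spec"))
  sys <- spec$system
  segs <- spec$protocol$segments
  t0 <- segs$start_s[1]
  horizon <- max(segs$end_s)
  times <- seq(t0, horizon, by = spec$sampling_interval_s)
  on_idx <- which(segs$power_W > 0)
  eta_per_cycle <- sys$eta *
    (1 - spec$bleaching_per_cycle)^(seq_along(on_idx) - 1)
  sched <- protocol_schedule(segs, t0, max(horizon, max(times)))
  # heat input per schedule piece, eta bleached per on-segment order
  on_counter <- 0
  q <- vapply(seq_along(sched$power), function(i) {
    p <- sched$power[i]
    if (p > 0) {
      on_counter <<- on_counter + 1
      eta_k <- sys$eta * (1 - spec$bleaching_per_cycle)^(on_counter - 1)
      p * (1 - 10^(-sys$absorbance)) * eta_k + sys$solvent_heat
    } else 0
  }, numeric(1))
  clean <- piecewise_exponential(times, sched$start, sched$end, q,
                                 hA = sys$hA, tau = sys$tau_s,
                                 ambient = sys$ambient_temp,
                                 init_temp = init_temp)
  noise <- if (spec$noise_sigma_K > 0)
    with_seed(spec$seed, stats::rnorm(length(times), 0,
                                      spec$noise_sigma_K))
  else rep(0, length(times))
  on_power <- if (length(on_idx)) segs$power_W[on_idx[1]] else 0
  dT_cycle <- (on_power * (1 - 10^(-sys$absorbance)) * eta_per_cycle +
                 sys$solvent_heat) / sys$hA
  list(trace = temperature_trace(times, clean + noise, label = label),
       noiseless = temperature_trace(times, clean,
                                     label = paste0(label, " (noiseless)")),
       truth = list(tau_s = sys$tau_s, hA = sys$hA,
                    eta_per_cycle = eta_per_cycle,
                    dT_max_per_cycle = dT_cycle))
}

#' Generate noisy calibration points on a known line
#'
#' @param slope True slope, absorbance per ug/mL, > 0.
#' @param intercept True intercept (baseline absorbance).
#' @param concentrations Concentrations in ug/mL at which to measure.
#' @param noise_sigma Gaussian absorbance noise sd, >= 0.
#' @param seed Integer seed.
#' @return Data frame with columns `conc_ug_per_mL`, `absorbance`.
#' @export
make_calibration_points <- function(slope, intercept, concentrations,
                                    noise_sigma = 0, seed = 1L) {
  stop_if_not_scalar(slope, "slope")
  stop_if_not_scalar(intercept, "intercept")
  stop_if_not_scalar(noise_sigma, "noise_sigma")
  if (slope <= 0) stop("`slope` must be > 0", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  noise <- if (noise_sigma > 0)
    with_seed(seed, stats::rnorm(length(concentrations), 0, noise_sigma))
  else rep(0, length(concentrations))
  data.frame(conc_ug_per_mL = concentrations,
             absorbance = slope * concentrations + intercept + noise)
}

#' Generate a synthetic viability plate table
#'
#' Sample absorbance is `control * viability / 100` plus Gaussian
#' noise, replicated per group.
#'
#' @param true_viability_by_group Named numeric vector of true
#'   viabilities in percent, >= 0.
#' @param control_absorbance Control-well absorbance, > 0.
#' @param noise_sigma Gaussian absorbance noise sd, >= 0.
#' @param replicates Replicates per group, >= 1.
#' @param seed Integer seed.
#' @return Data frame with columns `group`, `replicate`, `absorbance`
#'   and attribute `control_absorbance`.
#' @export
make_viability_plate <- function(true_viability_by_group,
                                 control_absorbance, noise_sigma = 0,
                                 replicates = 3, seed = 1L) {
  if (is.null(names(true_viability_by_group)) ||
      any(true_viability_by_group < 0))
    stop("`true_viability_by_group` must be a named vector of values >= 0",
         call. = FALSE)
  stop_if_not_scalar(control_absorbance, "control_absorbance")
  if (control_absorbance <= 0)
    stop("`control_absorbance` must be > 0", call. = FALSE)
  groups <- rep(names(true_viability_by_group), each = replicates)
  truth <- rep(true_viability_by_group, each = replicates)
  n <- length(groups)
  noise <- if (noise_sigma > 0)
    with_seed(seed, stats::rnorm(n, 0, noise_sigma))
  else rep(0, n)
  out <- data.frame(group = groups,
                    replicate = rep(seq_len(replicates),
                                    length(true_viability_by_group)),
                    absorbance = control_absorbance * truth / 100 + noise)
  rownames(out) <- NULL
  attr(out, "control_absorbance") <- control_absorbance
  out
}

#' Demo scenario mirroring a published dye-loaded carbon experiment
#'
#' Ships the package's reference scenario: an ICG-loaded porous-carbon
#' suspension and a pure-water control in 1-mL cuvettes under an
#' 808-nm laser at 2.5 W/cm^2 (1 cm^2 beam), 10 min on followed by
#' 10 min natural cooling, sampled every 60 s. The parameters are fixed
#' so that the noiseless sample trace rises from 26.3 to about 62 deg C
#' and the water control from 26.3 to about 26.8 deg C — the endpoint
#' behavior typical of such suspensions.
#'
#' @return A list with members `sample_system`, `water_system`
#'   ([thermal_system()]s), `protocol` (a [laser_protocol()]),
#'   `laser_power_W`, `laser_off_s` and `sampling_interval_s`.
#' @export
demo_scenario <- function() {
  hA <- 0.0418        # W/K, gives ~35.7 K rise at 600 s for this system
  sample_system <- thermal_system(
    heat_capacity_total = 4.2,   # ~1 mL water plus tube, J/K
    hA = hA, eta = 0.76, absorbance = 0.65,
    solvent_heat = 0.5 * hA,     # water control plateaus +0.5 K
    ambient_temp = 26.3)
  water_system <- thermal_system(
    heat_capacity_total = 4.2, hA = hA, eta = 0, absorbance = 0,
    solvent_heat = 0.5 * hA, ambient_temp = 26.3)
  list(sample_system = sample_system, water_system = water_system,
       protocol = cycled_protocol(power_W = 2.5, on_s = 600,
                                  off_s = 600, n_cycles = 1),
       laser_power_W = 2.5, laser_off_s = 600,
       sampling_interval_s = 60)
}

# internal: evaluate code with a temporary seed, restoring the session
# RNG state afterwards so generators are pure functions of their spec
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
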
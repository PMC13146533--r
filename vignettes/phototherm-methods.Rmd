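---
title: "Photothermal characterization: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photothermal characterization: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phototherm)
```

# The forward model and its assumptions

`phototherm` treats a laser-irradiated cuvette as a single lumped heat
capacity. The energy balance is

$$\sum_i m_i C_{p,i}\,\frac{dT}{dt} = Q_{NPs} + Q_s - hA\,(T - T_{surr}),$$

with three terms:

* $Q_{NPs} = I\,(1 - 10^{-A})\,\eta$ — the heat released by the
  photothermal agent. $I$ is the laser power in W, $A$ the sample
  absorbance at the laser wavelength (so $1-10^{-A}$ is the absorbed
  fraction), and $\eta \in [0,1]$ the conversion efficiency.
* $Q_s$ — heat absorbed by the solvent itself, in W. It represents
  light absorption, so it is gated by the laser: while the laser is off
  the whole source term is zero. (`input_power()` evaluates the formula
  as written, which reduces to $Q_s$ at zero power; the simulator
  applies the gating.)
* $hA\,(T - T_{surr})$ — Newtonian loss through the container. Only
  the product $hA$ (W/K) enters; $h$ and $A$ are not separately
  identifiable from bulk temperature data, so the package never
  represents them individually.

The model is linear in $T$ on every constant-power segment, so the
solution is exactly piecewise exponential: each segment relaxes toward
$T_{surr} + Q/hA$ with time constant $\tau = \sum m C_p / hA$,
continuously across boundaries. `simulate_trace()` evaluates this
closed form; a generic numeric ODE integrator appears only in the test
suite, as an independent oracle that the closed form must match to
within $10^{-6}$ K on multi-cycle protocols.

Lumping is the substantive physical assumption: one temperature for
the whole cuvette, a loss term linear in $\Delta T$ (no separate
radiative law), no spatial fields, and no convective transients. These
are the standard assumptions of cooling-curve efficiency estimation in
the photothermal literature.

Laser protocols are ordered on/off segments (`laser_protocol()`,
`cycled_protocol()`); power is stored in watts. Experiments are usually
reported as power densities (W/cm²), so the run configuration carries a
`beam_area_cm2` field (default 1 cm²) and derives
`laser_power_W = power_density × beam_area`; the beam area is rarely
reported alongside published traces, which is one reason printed
efficiencies are hard to reproduce from the literature (see
*Limitations*).

# The inverse pipeline

`estimate_efficiency()` chains five steps, each exported:

1. **Plateau rises.** $\Delta T_{max}$ for the sample and for a water
   reference measured under the identical protocol is the mean of the
   last $k$ samples of the laser-on window minus ambient (default
   $k = 3$, `plateau_k`). A single-sample maximum is upward-biased
   under noise; the trailing mean is not, provided the trace has
   plateaued. With fewer than $k$ on-window samples the maximum is used
   with a warning. The water rise is clamped at zero (with a flag) if
   noise drives the measured plateau slightly below ambient.
2. **Cooling extraction** (`extract_cooling()`): samples at or after
   shut-off, re-zeroed.
3. **Linearization** (`compute_theta()`):
   $\theta = (T - T_{surr})/(T_{max} - T_{surr})$. Points with
   $\theta \le$ `theta_floor` (default 0.05) are dropped — near
   ambient, the variance of $-\ln\theta$ diverges — as are points with
   $\theta > 1$ (e.g. the shut-off sample itself when it sits above
   the plateau mean). On noiseless data the floor is irrelevant (a
   tested invariant); under noise it stabilizes the regression.
4. **Regression** (`fit_time_constant()`): OLS of $t$ on $-\ln\theta$;
   the slope is $\tau$. An intercept is included by default even though
   the theory implies a through-origin line: it absorbs the constant
   offset introduced when $T_{max}$ is the plateau mean rather than the
   exact shut-off temperature, leaving the slope unbiased.
   `through_origin = TRUE` restores the textbook form.
5. **Efficiency** (`compute_hA()`, `compute_eta()`):
   $hA = \sum m C_p/\tau$, then
   $\eta = hA(\Delta T_{max,mix} - \Delta T_{max,H_2O}) / (I(1-10^{-A}))$.
   Estimates outside $[0,1]$ are returned flagged, not rejected —
   noise can push a legitimate estimate past a physical bound, and
   silently truncating would bias averages over replicates.

Ambient temperature comes from the configuration (or the first
sample), never from the trace tail: a 10-minute cooling window need
not reach ambient.

The estimator presumes the heating window actually plateaus. The
plateau mean underestimates $\Delta T_{max}$ by a factor of order
$e^{-t_{on}/\tau}$; for the sub-0.5% recovery the tests demand, the
laser-on window must span roughly $\ge 9\tau$. This is a property of
the method itself — published protocols choose 10-minute irradiation
precisely so that an "approximate plateau" is reached.

# Dye loading

Loading is quantified against a linear absorbance–concentration
calibration (`fit_calibration()`, with intercept by default since
instrument baselines are real). Two definitions:

* $DLE = 100 \cdot m_{loaded}/m_{fed}$ — fraction of the fed dye that
  ended up loaded;
* $DLC = 100 \cdot m_{loaded}/(m_{carrier} + m_{loaded})$ — dye mass as
  a fraction of the *loaded-particle* mass. The denominator includes
  the loaded dye; the two percentages are linked by the identity
  $DLC = 100\,(DLE \cdot fed)/(100\,carrier + DLE \cdot fed)$, which
  the test suite checks across random valid tuples.

Both direct (particle absorbance) and indirect (supernatant
absorbance; loaded = fed − found) assays are supported; the mode is an
explicit field because published wordings are often ambiguous about
which solution was measured. Percentages are reported at one decimal
place; full precision is kept internally.

# Photostability and power series

`segment_cycles()` cuts a multi-cycle trace at the protocol's known
on/off times — the experiments have controlled timing, so boundaries
are never inferred from the signal. The per-cycle peak is the maximum
sample of the heating window (the conventional "highest temperature of
the cycle"), and `peak_decay()` is first-cycle peak minus last-cycle
peak: a first-minus-last convention rather than a fitted trend, chosen
because with four cycles a trend fit adds variance without changing the
headline number. `power_series_summary()` applies the same plateau rule
across a laser power series and flags any violation of the strict
monotonicity the forward model guarantees.

# Bioassay summaries

CCK-8 viability is the plain absorbance ratio
$100 \cdot A_{sample}/A_{control}$, with optional blank subtraction
(supported because plate protocols differ; default 0) and a flag above
120%. Relative tumor volume is defined as $V(day)/V(day\,0)$ per
animal — the term is standard but rarely defined in print, so the
definition is stated here as an assumption — and summarized as group
mean ± sd per day. Caliper volume formulas are out of scope: volumes
are taken as recorded inputs.

# The synthetic-data generators

Every input the pipeline consumes can be generated with known ground
truth (`make_trace()`, `make_calibration_points()`,
`make_viability_plate()`), so the whole chain is testable without any
instrument data. Design choices:

* **Noise**: i.i.d. Gaussian on temperature, default
  $\sigma = 0.2$ K — typical precision of a handheld thermal imager;
  sampling default 60 s, the cadence such imagers log at. Drift and
  autocorrelation are deliberately not emulated.
* **Photobleaching**: geometric decay of $\eta$ per completed on/off
  cycle, $\eta_k = \eta\,(1-b)^{k-1}$ — the simplest phenomenology
  reproducing a monotone per-cycle peak loss. It is a generator
  device, not a mechanistic claim.
* **Determinism**: every generator is a pure function of its spec
  including the seed, and restores the session RNG state, so outputs
  are bitwise-reproducible.

`demo_scenario()` fixes a reference parameter set — $\sum mC_p = 4.2$
J/K (about 1 mL of water plus tube), $hA = 0.0418$ W/K
($\tau \approx 100$ s), $\eta = 0.76$, $A_{808} = 0.65$, $I = 2.5$ W
over 1 cm², $Q_s = 0.5\,hA$ — chosen once so that the noiseless sample
trace climbs from 26.3 °C to ≈62 °C in 10 min while the water control
reaches only ≈26.8 °C, endpoint behavior typical of strongly absorbing
dye-loaded carbon suspensions.

```{r demo}
demo <- demo_scenario()
t <- seq(0, 1200, by = 60)
sample_tr <- simulate_trace(demo$sample_system, demo$protocol, t)
water_tr <- simulate_trace(demo$water_system, demo$protocol, t)
c(sample_peak = max(sample_tr$temps), water_peak = max(water_tr$temps))
estimate_efficiency(sample_tr, water_tr, demo$laser_off_s, 4.2,
                    demo$laser_power_W, demo$sample_system$absorbance,
                    26.3)
```

What passing tests on synthetic data do show: the estimation procedure
is well-posed at the imager's own sampling rate — with
$\sigma = 0.2$ K noise, 60-s sampling and a 10-min cooling window, the
efficiency is recovered within a few percent on average over seeds.
What they do not show: robustness to convective transients, imager
drift, mis-stated heat capacities or beam areas, or non-exponential
cooling in real cuvettes.

# Numerical choices and degenerate inputs

* Temperatures are stored in °C, differences in K, times in seconds;
  powers in W. All unit conversions happen at the configuration layer.
* Simulation problem sizes in the tests and the acceptance script are
  modest by design (tens of samples per trace, 100-seed recovery
  studies); the closed-form simulator makes each evaluation trivial.
* Degenerate inputs fail loudly with named errors: protocols must be
  sorted and non-overlapping; traces strictly increasing in time
  (parse errors carry file and row); $\theta$ regressions need at
  least three retained points with variance in $-\ln\theta$;
  calibrations need three points over two distinct concentrations;
  loading masses must respect the balance (computed loads below zero
  clamp with a warning, above fed are errors); tumor records need a
  positive day-0 baseline per animal.
* Ties at cycle boundaries: a sample taken exactly at shut-off belongs
  to the heating window of the cycle it ends and is the $\theta > 1$
  candidate dropped by the linearization.

# Known limitations

* Single-exponential cooling only; no multi-compartment or spatially
  resolved extensions, and no Bayesian uncertainty on $\eta$ — point
  estimates with regression diagnostics.
* Published efficiency values can rarely be recomputed from a paper's
  text alone: they hinge on the absorbance at the laser line, the
  total heat capacity, the beam area and the raw traces, any of which
  may be unreported. The package's answer is the recovery study on
  synthetic data plus transparent diagnostics on real data, not a
  claim to reproduce any particular printed number.
* The strict CSV dialect (`time_s,temp_C`) means proprietary imager
  exports need a one-line conversion before ingestion.
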
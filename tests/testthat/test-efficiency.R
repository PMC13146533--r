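test_that("extract_cooling slices and re-zeroes the tail", {
  t <- seq(0, 1900, by = 100)  # 20 samples
  tr <- temperature_trace(t, 30 + sin(t / 500))
  cool <- extract_cooling(tr, 1000)
  expect_equal(length(cool$times), 10)
  expect_equal(cool$times[1], 0)
  expect_equal(cool$temps, tr$temps[t >= 1000])
  expect_error(extract_cooling(tr, 5000), "insufficient")
})

test_that("theta is the normalized driving force with floor and cap", {
  cool <- temperature_trace(c(0, 60, 120, 180),
                            c(62, 44.15, 30, 26.3))
  th <- compute_theta(cool, ambient_temp = 26.3, max_temp = 62)
  # endpoint: T = max -> theta 1; ambient sample dropped at the floor
  expect_equal(th$theta[1], 1)
  expect_equal(th$theta[2], 0.5)  # midpoint of the 26.3 -> 62 rise
  expect_equal(th$n_dropped_low, 1)
  expect_error(compute_theta(cool, 62, 26.3), "exceed")
})

test_that("theta reproduces the exponential law on noiseless cooling", {
  sys <- ref_system(tau_s = 200)
  t <- seq(0, 540, by = 60)
  cool <- analytic_cooling(sys, 62, t)
  th <- compute_theta(cool, 26.3, 62, theta_floor = 0.01)
  expect_equal(th$theta, exp(-t[seq_along(th$theta)] / 200),
               tolerance = 1e-12)
})

test_that("time-constant regression recovers tau exactly when exact", {
  t <- seq(0, 600, by = 60)
  th <- structure(list(times = t, theta = exp(-t / 200),
                       theta_floor = 0, n_dropped_low = 0,
                       n_dropped_high = 0), class = "theta_series")
  fit <- fit_time_constant(th)
  expect_equal(fit$tau_s, 200, tolerance = 1e-9)
  expect_equal(fit$intercept_s, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # constant series is degenerate
  th2 <- structure(list(times = t, theta = rep(0.5, length(t)),
                        theta_floor = 0, n_dropped_low = 0,
                        n_dropped_high = 0), class = "theta_series")
  expect_error(fit_time_constant(th2), "degenerate")
})

test_that("time-constant fit is scale-equivariant in time", {
  t <- seq(0, 600, by = 60)
  mk <- function(times) structure(
    list(times = times, theta = exp(-t / 200), theta_floor = 0,
         n_dropped_low = 0, n_dropped_high = 0),
    class = "theta_series")
  tau1 <- fit_time_constant(mk(t))$tau_s
  tau3 <- fit_time_constant(mk(3 * t))$tau_s
  expect_equal(tau3, 3 * tau1, tolerance = 1e-9)
})

test_that("noisy cooling still recovers tau within 5% on average", {
  sys <- ref_system(tau_s = 300)
  t <- seq(0, 600, by = 60)  # 10-min window at 60-s sampling
  clean <- analytic_cooling(sys, 62, t)
  taus <- vapply(1:100, function(seed) {
    noisy <- temperature_trace(
      t, clean$temps + phototherm:::with_seed(seed,
        stats::rnorm(length(t), 0, 0.2)))
    th <- compute_theta(noisy, 26.3, 62)
    fit_time_constant(th)$tau_s
  }, numeric(1))
  expect_lt(abs(mean(taus) - 300) / 300, 0.05)
})

test_that("hA follows from the time constant and heat capacity", {
  expect_equal(compute_hA(300, 4.2), 0.014)
  expect_equal(compute_hA(4.2, 4.2), 1)
  # inverse pair round-trips
  hA <- compute_hA(287.3, 4.2)
  expect_equal(4.2 / hA, 287.3)
  expect_error(compute_hA(-1, 4.2), "> 0")
})

test_that("eta evaluates the steady-state balance", {
  expect_equal(compute_eta(0.015, 35.7, 0.5, 1.2, 1.0),
               0.015 * 35.2 / (1.2 * 0.9))  # 0.4889
  expect_equal(compute_eta(0.015, 10, 10, 1, 1), 0)
  # balance identity: numerator equals denominator -> eta = 1
  expect_equal(compute_eta(0.02, 45.5, 0.5, 1, 0.9 / 0.02 / 45),
               1, tolerance = 1e-12)
  expect_error(compute_eta(0.015, 35.7, 0.5, 1.2, 0), "absorbance")
  expect_warning(compute_eta(1, 50, 0, 1, 1), "exceeds 1")
})

test_that("noiseless round trip recovers tau, hA and eta within 0.5%", {
  cases <- list(
    list(tau = 50, eta = 0.76, A = 0.65),
    list(tau = 80, eta = 0.45, A = 1.2),
    list(tau = 100, eta = 0.28, A = 0.9))
  for (cs in cases) {
    sys <- ref_system(tau_s = cs$tau, eta = cs$eta, absorbance = cs$A,
                      solvent_heat = 0.01)
    water <- thermal_system(sys$heat_capacity_total, sys$hA, eta = 0,
                            absorbance = 0, solvent_heat = 0.01,
                            ambient_temp = 26.3)
    on_s <- 10 * cs$tau
    prot <- cycled_protocol(2.5, on_s = on_s, off_s = 6 * cs$tau)
    t <- seq(0, on_s + 6 * cs$tau, by = cs$tau / 10)
    est <- estimate_efficiency(
      simulate_trace(sys, prot, t), simulate_trace(water, prot, t),
      laser_off_s = on_s, heat_capacity_total = 4.2,
      laser_power = 2.5, absorbance = cs$A, ambient_temp = 26.3)
    expect_lt(abs(est$tau_s - cs$tau) / cs$tau, 0.005)
    expect_lt(abs(est$hA - sys$hA) / sys$hA, 0.005)
    expect_lt(abs(est$eta - cs$eta) / cs$eta, 0.005)
  }
})

test_that("identical sample and water traces give eta = 0", {
  sys <- ref_system(tau_s = 100)
  prot <- cycled_protocol(2.5, on_s = 600, off_s = 600)
  t <- seq(0, 1200, by = 30)
  tr <- simulate_trace(sys, prot, t)
  est <- estimate_efficiency(tr, tr, 600, 4.2, 2.5, 0.65, 26.3)
  expect_equal(est$eta, 0)
})

test_that("eta estimate survives noise at the imager's sampling rate", {
  # sigma = 0.2 K, 60-s sampling, 10-min cooling window
  sys <- ref_system(tau_s = 300, eta = 0.76, absorbance = 0.65,
                    solvent_heat = 0.005)
  water <- thermal_system(4.2, sys$hA, eta = 0, absorbance = 0,
                          solvent_heat = 0.005, ambient_temp = 26.3)
  prot <- cycled_protocol(2.5, on_s = 1800, off_s = 600)
  etas <- vapply(1:100, function(seed) {
    spec_s <- trace_gen_spec(sys, prot, sampling_interval_s = 60,
                             noise_sigma_K = 0.2, seed = seed)
    spec_w <- trace_gen_spec(water, prot, sampling_interval_s = 60,
                             noise_sigma_K = 0.2, seed = seed + 50000)
    estimate_efficiency(make_trace(spec_s)$trace,
                        make_trace(spec_w)$trace,
                        1800, 4.2, 2.5, 0.65, 26.3)$eta
  }, numeric(1))
  expect_lt(abs(mean(etas) - 0.76) / 0.76, 0.05)
})

test_that("theta floor is irrelevant on noiseless data", {
  sys <- ref_system(tau_s = 120)
  prot <- cycled_protocol(2.5, on_s = 1200, off_s = 720)
  t <- seq(0, 1920, by = 30)
  tr <- simulate_trace(sys, prot, t)
  water <- thermal_system(4.2, sys$hA, eta = 0, absorbance = 0,
                          ambient_temp = 26.3)
  wtr <- simulate_trace(water, prot, t)
  est05 <- estimate_efficiency(tr, wtr, 1200, 4.2, 2.5, 0.65, 26.3,
                               theta_floor = 0.05)
  est10 <- estimate_efficiency(tr, wtr, 1200, 4.2, 2.5, 0.65, 26.3,
                               theta_floor = 0.10)
  expect_lt(abs(est05$tau_s - est10$tau_s) / est05$tau_s, 1e-6)
})

test_that("eta is invariant to a common ambient offset", {
  sys <- ref_system(tau_s = 90)
  water <- thermal_system(4.2, sys$hA, eta = 0, absorbance = 0,
                          ambient_temp = 26.3)
  prot <- cycled_protocol(2.5, on_s = 900, off_s = 540)
  t <- seq(0, 1440, by = 30)
  tr <- simulate_trace(sys, prot, t)
  wtr <- simulate_trace(water, prot, t)
  est <- estimate_efficiency(tr, wtr, 900, 4.2, 2.5, 0.65, 26.3)
  shift <- 4.7
  tr2 <- temperature_trace(tr$times, tr$temps + shift)
  wtr2 <- temperature_trace(wtr$times, wtr$temps + shift)
  est2 <- estimate_efficiency(tr2, wtr2, 900, 4.2, 2.5, 0.65,
                              26.3 + shift)
  expect_equal(est2$eta, est$eta, tolerance = 1e-9)
})
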
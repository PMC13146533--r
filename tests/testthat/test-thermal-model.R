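test_that("input power follows the absorbed-fraction law", {
  # eta = 0: no photothermal heating
  s0 <- thermal_system(4.2, 0.014, eta = 0, absorbance = 1)
  expect_equal(input_power(s0, 1), 0)
  # full-absorption limit: A = 10 absorbs essentially everything
  s1 <- thermal_system(4.2, 0.014, eta = 1, absorbance = 10)
  expect_equal(input_power(s1, 1), 1, tolerance = 1e-9)
  # generic evaluation with solvent term
  s2 <- thermal_system(4.2, 0.014, eta = 0.5, absorbance = 1,
                       solvent_heat = 0.01)
  expect_equal(input_power(s2, 2), 2 * 0.9 * 0.5 + 0.01)
  expect_error(input_power(s2, -1), "laser_power")
})

test_that("steady-state rise is input power over hA", {
  s <- thermal_system(4.2, 0.02, eta = 1, absorbance = 10)
  expect_equal(steady_state_delta(s, 1), input_power(s, 1) / 0.02)
  s0 <- thermal_system(4.2, 0.02, eta = 0, absorbance = 1)
  expect_equal(steady_state_delta(s0, 5), 0)
  s2 <- thermal_system(4.2, 0.015, eta = 0.5, absorbance = 1)
  expect_equal(steady_state_delta(s2, 1), 0.45 / 0.015)  # 30 K
})

test_that("single-segment heating matches the closed form", {
  sys <- ref_system(tau_s = 300, solvent_heat = 0)
  dT_max <- steady_state_delta(sys, 2.5)
  prot <- laser_protocol(data.frame(start_s = 0, end_s = 1200,
                                    power_W = 2.5))
  t <- seq(0, 1200, by = 30)
  tr <- simulate_trace(sys, prot, t)
  expect_equal(tr$temps,
               26.3 + dT_max * (1 - exp(-t / 300)),
               tolerance = 1e-9)
  # value at t = tau
  expect_equal(tr$temps[t == 300],
               26.3 + dT_max * (1 - exp(-1)), tolerance = 1e-9)
})

test_that("a known rise evaluates to the frozen closed-form value", {
  # tau = 300 s, dT_max = 35.7 K, ambient 26.3 degC, 600 s of heating:
  # T = 26.3 + 35.7 (1 - e^-2) = 57.1685 degC
  hA <- 0.014
  q <- 35.7 * hA  # power tuned so the steady-state rise is exactly 35.7
  sys <- thermal_system(4.2, hA, eta = 1, absorbance = 10,
                        ambient_temp = 26.3)
  prot <- laser_protocol(data.frame(start_s = 0, end_s = 600,
                                    power_W = q / (1 - 10^-10)))
  tr <- simulate_trace(sys, prot, c(0, 600))
  expect_equal(tr$temps[2], 26.3 + 35.7 * (1 - exp(-2)),
               tolerance = 1e-7)
  expect_equal(tr$temps[2], 57.1685, tolerance = 1e-4)
})

test_that("zero power leaves the system at ambient", {
  sys <- ref_system()
  prot <- laser_protocol(data.frame(start_s = 0, end_s = 600,
                                    power_W = 0))
  tr <- simulate_trace(sys, prot, seq(0, 600, by = 60))
  expect_equal(tr$temps, rep(26.3, 11))
})

test_that("analytic cooling obeys the exponential decay law", {
  sys <- ref_system(tau_s = 300)
  # frozen value: start 62, ambient 26.3, one time constant later
  tr <- analytic_cooling(sys, 62, c(0, 300))
  expect_equal(tr$temps[2], 26.3 + 35.7 / exp(1), tolerance = 1e-9)
  expect_equal(tr$temps[2], 39.4328, tolerance = 1e-4)
  # half-life identity
  tr2 <- analytic_cooling(sys, 62, c(0, 300 * log(2)))
  expect_equal(tr2$temps[2] - 26.3, 35.7 / 2, tolerance = 1e-9)
  # start at ambient: constant
  tr3 <- analytic_cooling(sys, 26.3, c(0, 100, 500))
  expect_equal(tr3$temps, rep(26.3, 3))
  expect_error(analytic_cooling(sys, 20, c(0, 100)), "ambient")
})

test_that("laser-off simulation agrees with analytic cooling", {
  sys <- ref_system(tau_s = 250)
  prot <- cycled_protocol(power_W = 2.5, on_s = 600, off_s = 600)
  t_all <- seq(0, 1200, by = 20)
  tr <- simulate_trace(sys, prot, t_all)
  T_off <- tr$temps[t_all == 600]
  cool_times <- t_all[t_all >= 600]
  expected <- analytic_cooling(sys, T_off, cool_times - 600)
  expect_equal(tr$temps[t_all >= 600], expected$temps,
               tolerance = 1e-9)
})

test_that("multi-cycle simulation matches a numeric ODE oracle", {
  skip_if_not_installed("deSolve")
  sys <- ref_system(tau_s = 180, solvent_heat = 0.02)
  prot <- cycled_protocol(power_W = 2.0, on_s = 600, off_s = 600,
                          n_cycles = 4)
  t <- seq(0, 4800, by = 60)
  tr <- simulate_trace(sys, prot, t)
  expect_equal(tr$temps, ode_oracle(sys, prot, t), tolerance = 1e-6)
})

test_that("steady state is monotone in power and trace stays in bounds", {
  sys <- ref_system()
  powers <- c(0.5, 1.0, 1.5, 2.0, 2.5)
  dT <- vapply(powers, function(p) steady_state_delta(sys, p),
               numeric(1))
  expect_true(all(diff(dT) > 0))
  prot <- cycled_protocol(power_W = 2.5, on_s = 600, off_s = 600,
                          n_cycles = 2)
  tr <- simulate_trace(sys, prot, seq(0, 2400, by = 10))
  expect_true(all(tr$temps >= 26.3 - 1e-12))
  expect_true(all(tr$temps <= 26.3 + steady_state_delta(sys, 2.5) + 1e-12))
})

test_that("simulation rejects bad sampling requests", {
  sys <- ref_system()
  prot <- cycled_protocol(power_W = 1, on_s = 600, off_s = 600)
  expect_error(simulate_trace(sys, prot, numeric(0)), "non-empty")
  expect_error(simulate_trace(sys, prot, c(-100, 0, 100)),
               "protocol span")
})
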
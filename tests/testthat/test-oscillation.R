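test_that("spectrum nails a pure tone and prefers the stronger of two tones", {
  t <- 0:4095
  sp <- power_spectrum(sin(2 * pi * t / 90), dt = 1)
  expect_equal(attr(sp, "peak_period"), 90, tolerance = 0.1 / 90)

  # brute force over constructed two-tone signals with a 2:1 power ratio
  for (p2 in c(45, 130, 220)) {
    x <- sqrt(2) * sin(2 * pi * t / 90) + sin(2 * pi * t / p2 + 0.7)
    sp2 <- power_spectrum(x, dt = 1)
    expect_equal(attr(sp2, "peak_period"), 90, tolerance = 0.01)
  }
  expect_error(power_spectrum(rep(1, 128), dt = 1), "flat")
  expect_error(power_spectrum(sin(1:32), dt = 1), "64 samples")
})

test_that("model spectrum carries harmonics of a dominant fundamental", {
  sp <- power_spectrum(sim_37())
  g <- glance(sp)
  expect_true(g$peak_is_lowest)
  f0 <- g$peak_frequency
  # power at the second harmonic stands far above the local background
  p2 <- sp$power[which.min(abs(sp$frequency - 2 * f0))]
  bg <- median(sp$power[sp$frequency > 2.2 * f0 & sp$frequency < 3 * f0])
  expect_gt(p2, 10 * bg)
})

test_that("oscillation amplitude: zero at a fixed point, larger cold than hot", {
  fx <- simulate_nfkb(forcing = forcing_protocol(tnf_base = 0),
                      t_end = 10000, transient_cut = 8000)
  expect_lt(oscillation_amplitude(fx, check_window = FALSE), 1e-6)

  a32 <- oscillation_amplitude(sim_at(32))
  a395 <- oscillation_amplitude(sim_at(39.5))
  expect_gt(a32, a395)

  # peak/trough detection route agrees with the max-min route within 1%
  w <- trajectory_window(sim_37())
  pk <- nfkbtherm:::find_peaks(w$N_n, min_prominence = 0.05 * diff(range(w$N_n)))
  tr <- nfkbtherm:::find_peaks(-w$N_n, min_prominence = 0.05 * diff(range(w$N_n)))
  via_peaks <- max(pk$value) - min(-tr$value)
  expect_equal(via_peaks, oscillation_amplitude(sim_37()), tolerance = 0.01)
})

test_that("mean |dN/dt| vanishes at the fixed point and matches finite differences", {
  fx <- simulate_nfkb(forcing = forcing_protocol(tnf_base = 0),
                      t_end = 10000, transient_cut = 8000)
  expect_lt(mean_abs_derivative(fx), 1e-8)

  traj <- sim_37()
  mad_rhs <- mean_abs_derivative(traj)
  w <- trajectory_window(traj)
  mad_fd <- mean(abs(diff(w$N_n)) / diff(w$time))
  expect_equal(mad_rhs, mad_fd, tolerance = 0.01)
})

test_that("mean |dN/dt| rises sharply across the oscillation onset", {
  below <- mean_abs_derivative(sim_at(37, tnf = 0.03,
                                      t_end = 30000, transient_cut = 20000))
  above <- mean_abs_derivative(sim_at(37, tnf = 0.15,
                                      t_end = 30000, transient_cut = 20000))
  expect_gt(above, 50 * below)
})

test_that("Hopf threshold is monotone in temperature and converged", {
  h <- vapply(c(32, 37, 39.5), function(Tc) {
    hopf_threshold(Tc, bracket = c(1e-3, 0.8))
  }, numeric(1))
  expect_true(all(diff(h) > 0))
  # threshold at 32 sits below the flow-protocol drive, at 37 near it
  expect_lt(h[1], tnf_from_dose(1))

  # convergence: extending the evaluation horizon moves TNF* by < 1e-3
  h37b <- hopf_threshold(37, bracket = c(1e-3, 0.8),
                         t_end = 60000, transient_cut = 20000)
  expect_lt(abs(h37b - h[2]), 1e-3)

  # supercritical onset: amplitude explodes across the threshold
  amp_lo <- oscillation_amplitude(sim_at(37, tnf = 0.95 * h[2],
                                         t_end = 30000, transient_cut = 20000),
                                  check_window = FALSE)
  amp_hi <- oscillation_amplitude(sim_at(37, tnf = 1.05 * h[2],
                                         t_end = 30000, transient_cut = 20000),
                                  check_window = FALSE)
  expect_gt(amp_hi, 10 * amp_lo)
})

test_that("Hopf bracket errors name the failing endpoint", {
  expect_error(hopf_threshold(37, bracket = c(0.3, 0.8), t_end = 12000,
                              transient_cut = 6000),
               "TNF = 0.3 is oscillating")
})

test_that("period decreases with temperature at every TNF level; estimators agree", {
  sw <- sweep_period_temperature(temperatures = c(32, 34.5, 37, 39.5),
                                 tnf_levels = c(0.2, 0.5, 1.0),
                                 t_end = 8000)
  for (tnf in unique(sw$tnf)) {
    per <- sw$period_min[sw$tnf == tnf]
    expect_true(all(diff(per) < 0), label = paste("TNF", tnf))
  }
  # spectral vs inter-peak period at 37 within 2%
  traj <- sim_37()
  expect_equal(dominant_period(traj), mean_peak_interval(traj),
               tolerance = 0.02)
})

test_that("period slope fit behaves like a broom-style model object", {
  sw <- sweep_period_temperature(temperatures = seq(32, 39.5, by = 2.5),
                                 tnf_levels = 0.5, t_end = 8000)
  fit <- fit_period_slope(sw, tnf = 0.5)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  g <- glance(fit)
  expect_lt(g$slope_min_per_C, 0)
  expect_gt(g$r.squared, 0.9)
})
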
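test_that("parameter defaults validate and reject bad input", {
  p <- nfkb_params()
  expect_s3_class(p, "nfkb_params")
  expect_length(unlist(p), 15L)
  expect_error(nfkb_params(k_foo = 1), "unknown parameter")
  expect_error(nfkb_params(k_i = -1), "strictly positive")
})

test_that("rhs trivial structure: no IKK activation without TNF, repelling N_n boundary", {
  p <- nfkb_params()
  f0 <- forcing_protocol(tnf_base = 0)
  s <- c(N_n = 0.2, I_m = 0.05, I = 1, IKK_a = 0, IKK_i = 0)
  d <- nfkb_rhs(s, 0, p, f0)
  expect_equal(unname(d[["IKK_a"]]), 0)
  expect_equal(unname(d[["IKK_i"]]), 0)

  s2 <- c(N_n = 0, I_m = 0.05, I = 1, IKK_a = 0.1, IKK_i = 0.1)
  d2 <- nfkb_rhs(s2, 0, p)
  expect_equal(unname(d2[["N_n"]]),
               p$k_Nin * p$N_tot * p$K_I / (p$K_I + 1), tolerance = 1e-12)
  expect_gt(d2[["N_n"]], 0)
})

test_that("rhs matches a term-by-term hand evaluation at the reference state", {
  p <- nfkb_params()
  s <- c(N_n = 0.1, I_m = 0.01, I = 0.5, IKK_a = 0.1, IKK_i = 0.1)
  TNF <- 0.5
  # independent hand evaluation of each term
  IKK_n <- 2.0 - 0.1 - 0.1
  exp_dN <- 5.4 * (1 - 0.1) * 0.035 / (0.035 + 0.5) -
    0.018 * 0.5 * 0.1 / (0.029 + 0.1)
  exp_dIm <- 1.03 * 0.1^2 - 0.017 * 0.01
  exp_dI <- 0.24 * 0.01 - 1.05 * 0.1 * (1 - 0.1) * 0.5 / (0.035 + 0.5)
  exp_dKa <- 0.24 * TNF * IKK_n - 0.18 * 0.1
  exp_dKi <- 0.18 * 0.1 - 0.036 * 0.1 * 0.0018 / (0.0018 + 0.0026 * TNF)
  d <- nfkb_rhs(s, 0, p, forcing_protocol(tnf_base = TNF))
  expect_equal(unname(d),
               c(exp_dN, exp_dIm, exp_dI, exp_dKa, exp_dKi),
               tolerance = 1e-12)
  expect_error(nfkb_rhs(c(NaN, 0, 0, 0, 0), 0, p), "non-finite")
})

test_that("R and compiled right-hand sides integrate to the same trajectory", {
  f <- forcing_protocol(tnf_base = 0.5, temp_mode = "sinusoid",
                        temp_amplitude = 1, temp_frequency = 0.01)
  a <- simulate_nfkb(forcing = f, t_end = 600, transient_cut = 0)
  b <- simulate_nfkb(forcing = f, t_end = 600, transient_cut = 0, engine = "R")
  expect_lt(max(abs(a$N_n - b$N_n)), 1e-6)
  expect_lt(max(abs(a$IKK_i - b$IKK_i)), 1e-6)
})

test_that("IKK pool is conserved exactly and states stay in bounds", {
  traj <- sim_37()
  # IKK_n is derived, never integrated: re-deriving it reproduces the
  # stored column bit for bit
  ikk_tot <- attr(traj, "params")$IKK_tot
  expect_identical(max(abs((ikk_tot - traj$IKK_a - traj$IKK_i) -
                             traj$IKK_n)), 0)
  for (v in c("N_n", "I_m", "I", "IKK_a", "IKK_i")) {
    expect_true(all(traj[[v]] >= -1e-9))
  }
  expect_true(all(traj$N_n <= attr(traj, "params")$N_tot + 1e-9))
})

test_that("identical simulate calls are bit-identical; solver is deterministic", {
  a <- simulate_nfkb(t_end = 2500)
  b <- simulate_nfkb(t_end = 2500)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("without TNF the system relaxes to a fixed point", {
  traj <- simulate_nfkb(forcing = forcing_protocol(tnf_base = 0),
                        t_end = 10000, transient_cut = 8000)
  w <- trajectory_window(traj)
  expect_lt(diff(range(w$N_n)), 1e-6)
})

test_that("sustained oscillation at 37 degC has period near 100 min, peaks regular", {
  traj <- sim_37()
  per <- dominant_period(traj)
  expect_gt(per, 85)
  expect_lt(per, 125)
  # once converged onto the cycle the orbit is periodic: successive
  # (sub-sample refined) peak intervals vary < 1%
  long <- simulate_nfkb(t_end = 12000, transient_cut = 6000)
  w <- trajectory_window(long)
  pk <- nfkbtherm:::find_peaks(w$N_n, min_prominence = 0.05 * diff(range(w$N_n)))
  t_ref <- vapply(pk$idx, function(i) {
    w$time[i] + nfkbtherm:::parabolic_offset(w$N_n[i - 1], w$N_n[i],
                                             w$N_n[i + 1])
  }, numeric(1))
  iv <- diff(t_ref)
  expect_lt(max(abs(iv - mean(iv))) / mean(iv), 0.01)
})

test_that("adaptive solver agrees with an independent fixed-step RK4 oracle", {
  rk <- rk4_integrate(default_init(), t_end = 1000, dt = 0.001,
                      p = nfkb_params(), tnf = 0.5)
  traj <- simulate_nfkb(t_end = 1000, transient_cut = 0)
  ref <- as.matrix(traj[traj$time %in% rk$time,
                        c("N_n", "I_m", "I", "IKK_a", "IKK_i")])
  expect_lt(max(abs(ref - rk$state)), 1e-5)
})

test_that("TNF forcing modes evaluate as specified", {
  fs <- forcing_protocol(tnf_mode = "sinusoid", tnf_base = 0.5,
                         tnf_amplitude = 0.7, tnf_period = 100)
  expect_equal(tnf_at(fs, 25), 0.5 + 0.7, tolerance = 1e-12)
  expect_equal(tnf_at(fs, 75), 0, tolerance = 1e-12) # clamped at zero
  fst <- forcing_protocol(tnf_mode = "steps", tnf_base = 0,
                          tnf_steps = data.frame(time = c(-2, 38),
                                                 level = c(0.5, 0.9)))
  expect_equal(tnf_at(fst, c(-5, 0, 38, 100)), c(0, 0.5, 0.9, 0.9))
  ft <- forcing_protocol(temp_mode = "sinusoid", temp_base = 37,
                         temp_amplitude = 2, temp_frequency = 0.01)
  expect_equal(temperature_at(ft, 25), 39, tolerance = 1e-12)
})

test_that("trajectory writer emits the canonical CSV header", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(simulate_nfkb(t_end = 2100, dt_out = 50), path)
  expect_identical(readLines(path, n = 1),
                   "time_min,N_n,I_m,I,IKK_a,IKK_i,TNF,temperature_C")
})
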
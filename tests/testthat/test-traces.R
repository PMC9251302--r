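test_that("moving average follows the shrinking-window smoothing convention", {
  expect_identical(moving_average(rep(2, 10), 4), rep(2, 10))
  x <- rnorm(20)
  expect_identical(moving_average(x, 1), x)
  # linear ramps are preserved exactly, endpoints included
  expect_equal(moving_average(c(1, 2, 3, 4, 5), 3), c(1, 2, 3, 4, 5),
               tolerance = 1e-12)
  # even span reduces to span - 1: span 4 equals span 3
  expect_identical(moving_average(x, 4), moving_average(x, 3))
  # hand-computed interior/edge windows
  expect_equal(moving_average(c(4, 0, 8, 2, 6), 3),
               c(4, 4, 10 / 3, 16 / 3, 6), tolerance = 1e-12)
  expect_error(moving_average(1:3, 5), "smaller")
})

test_that("detrending is linear, kills trends and keeps the oscillation", {
  expect_equal(detrend_trace(rep(3, 30)), rep(0, 30), tolerance = 1e-12)
  ramp <- detrend_trace(seq(0, 5, length.out = 40))
  expect_equal(ramp[7:34], rep(0, 28), tolerance = 1e-12) # interior zeros

  x <- rnorm(50); y <- rnorm(50)
  expect_equal(detrend_trace(2 * x + 3 * y),
               2 * detrend_trace(x) + 3 * detrend_trace(y),
               tolerance = 1e-12)

  # slow drift attenuated > 5x, oscillation kept within 10% (interior)
  t <- seq(0, 1430, by = 10)
  osc <- sin(2 * pi * t / 100)
  drift <- 0.8 * sin(2 * pi * t / 2000)
  out <- detrend_trace(osc + drift)
  ref <- detrend_trace(osc)
  interior <- 8:(length(t) - 7)
  expect_lt(max(abs(out - ref)[interior]), 0.8 / 5)
  expect_gt(diff(range(ref[interior])), 0.9 * diff(range(osc)) * 0.5)
})

test_that("extract_period recovers tones, honours the override band and noise floor", {
  t <- seq(0, 710, by = 10)
  tone <- tibble::tibble(time_min = t, ratio = 1 + 0.3 * sin(2 * pi * t / 90))
  pe <- extract_period(tone)
  expect_false(pe$no_period)
  # within one (unpadded) spectral bin of 90 min
  expect_lt(abs(pe$frequency_per_min - 1 / 90), pe$freq_resolution)
  expect_true(pe$plausible)

  # invariance under affine intensity changes
  tone2 <- tone; tone2$ratio <- 5 * tone$ratio + 2
  expect_equal(extract_period(tone2)$period_min, pe$period_min,
               tolerance = 1e-9)

  # a printed-spectrum consistency check: a tone at 8.26e-3 / min reads
  # back as a ~121-min period
  t2 <- seq(0, 1990, by = 10)
  tone3 <- tibble::tibble(time_min = t2,
                          ratio = 1 + 0.4 * sin(2 * pi * 8.26e-3 * t2))
  expect_equal(extract_period(tone3)$period_min, 1 / 8.26e-3,
               tolerance = 0.01)

  # override band picks the in-band peak and flags itself
  two <- tibble::tibble(time_min = t2,
                        ratio = 1 + 0.5 * sin(2 * pi * t2 / 300) +
                          0.3 * sin(2 * pi * t2 / 95))
  pe_o <- extract_period(two, override_band = c(1 / 150, 1 / 50))
  expect_true(pe_o$used_override)
  expect_equal(pe_o$period_min, 95, tolerance = 0.05)

  # an impulse (one bright frame, a common imaging artefact) has an
  # exactly flat spectrum: no peak clears the 3x-median noise floor
  impulse <- c(1, rep(0, length(t2) - 1))
  expect_true(extract_period(tibble::tibble(time_min = t2,
                                            ratio = impulse))$no_period)
})

test_that("generated traces respect the sampling, positivity and seeding contracts", {
  tr <- generate_trace("flow", temperature = 34.5, seed = 11)
  expect_true(all(tr$ratio > 0))
  expect_identical(tr$time_min[1], 0)
  expect_true(all(diff(tr$time_min) == 10))
  expect_equal(tr$ratio, tr$I_N / tr$I_C, tolerance = 1e-12)

  tr_same <- generate_trace("flow", temperature = 34.5, seed = 11)
  expect_identical(as.data.frame(tr), as.data.frame(tr_same))
  tr_other <- generate_trace("flow", temperature = 34.5, seed = 12)
  expect_false(identical(tr$ratio, tr_other$ratio))
  expect_error(generate_trace("flow", duration = 300), "duration")
})

test_that("addition protocols show the right number of enhanced initial peaks", {
  for (Tc in c(32, 37, 39.5)) {
    for (proto in c("single", "double")) {
      tr <- generate_trace(proto, temperature = Tc, noise_sd = 0,
                           drift_sd = 0, seed = 1)
      pk <- nfkbtherm:::find_peaks(tr$ratio,
                                   min_prominence = 0.05 * diff(range(tr$ratio)))
      h <- pk$value
      later_med <- median(h[-(1:2)])
      n_enh <- sum(h > 1.25 * later_med)
      expect_identical(n_enh, if (proto == "double") 2L else 1L,
                       info = sprintf("%s at %.1f degC", proto, Tc))
      # the enhanced peaks are the initial ones
      expect_true(all(which(h > 1.25 * later_med) <= 2))
    }
  }
})

test_that("noiseless round trip recovers the generator truth within one bin", {
  for (proto in c("single", "double", "flow")) {
    for (Tc in c(32, 37, 39.5)) {
      tr <- generate_trace(proto, temperature = Tc, noise_sd = 0,
                           drift_sd = 0, seed = 1)
      pe <- extract_period(tr)
      expect_false(pe$no_period)
      expect_lt(abs(pe$frequency_per_min - 1 / attr(tr, "true_period")),
                pe$freq_resolution,
                label = sprintf("%s / %.1f degC", proto, Tc))
    }
  }
})

test_that("cohorts: deterministic seeding, small recovery bias, temperature trend", {
  co <- generate_cohort(12, "single", 37, seed = 5)
  expect_length(co$traces, 12L)
  # first cell reproducible from the derived seed and jittered constants
  cp <- nfkbtherm:::cohort_cell_params(5, 12)
  tr1 <- generate_trace("single", 37, seed = cp$seed[1],
                        ratio_c = cp$ratio_c[1], ratio_b = cp$ratio_b[1])
  expect_identical(as.data.frame(co$traces[[1]]), as.data.frame(tr1))

  st <- cohort_period_stats(co)
  expect_identical(st$n, 12L)
  truth <- mean(co$manifest$true_period_min)
  expect_lt(abs(st$mean_period_min - truth) / truth, 0.05)

  co32 <- generate_cohort(8, "flow", 32, seed = 9)
  co395 <- generate_cohort(8, "flow", 39.5, seed = 9)
  s32 <- cohort_period_stats(co32)
  s395 <- cohort_period_stats(co395)
  expect_gt(s32$mean_period_min, s395$mean_period_min)

  tt <- compare_cohort_periods(co32, co395)
  expect_lt(tt$p.value, 0.05)
  expect_gt(tt$mean_a, tt$mean_b)
})

test_that("identical traces give zero period spread", {
  tr <- generate_trace("flow", 37, seed = 3)
  st <- cohort_period_stats(list(tr, tr, tr))
  expect_identical(st$sd_period_min, 0)
})

test_that("trace CSVs and the cohort manifest round-trip through disk", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(3, "flow", 37, seed = 2, duration = 700)
  write_traces(co, dir)
  expect_length(list.files(dir, pattern = "^cell_"), 3L)
  back <- read_trace(file.path(dir, "cell_001.csv"))
  expect_equal(back$ratio, co$traces[[1]]$ratio, tolerance = 1e-9)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_identical(nrow(man), 3L)
  expect_true(all(c("seed", "true_period_min") %in% names(man)))

  # ratio-only files are accepted too
  p2 <- file.path(dir, "ratio_only.csv")
  readr::write_csv(tibble::tibble(time_min = co$traces[[1]]$time_min,
                                  ratio = co$traces[[1]]$ratio), p2)
  expect_equal(read_trace(p2)$ratio, co$traces[[1]]$ratio, tolerance = 1e-9)
})
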
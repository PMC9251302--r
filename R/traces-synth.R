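#' Map a TNF-alpha dose to the model's dimensionless drive
#'
#' Saturating conversion `dose / (dose + half_dose)`: 10 ng/ml maps to
#' 0.5 (the baseline drive of the addition protocols), 18 ng/ml to about
#' 0.64 and the 1 ng/ml flow plateau to about 0.09, which sits above the
#' 37 degC oscillation onset.
#'
#' @param dose_ng TNF-alpha concentration, ng/ml.
#' @param half_dose_ng dose giving drive 0.5.
#' @return The dimensionless TNF drive.
#' @export
tnf_from_dose <- function(dose_ng, half_dose_ng = 10) {
  stopifnot(all(dose_ng >= 0), half_dose_ng > 0)
  dose_ng / (dose_ng + half_dose_ng)
}

# abrupt addition times and the protocol's final TNF drive
protocol_steps <- function(protocol, doses) {
  switch(protocol,
    single = list(additions = -2, level = tnf_from_dose(doses$single)),
    double = list(additions = c(-2, 38),
                  level = tnf_from_dose(doses$double2)),
    flow = list(additions = numeric(), level = tnf_from_dose(doses$flow)),
    abort(sprintf("unknown protocol: '%s'", protocol))
  )
}

# Noiseless nuclear-NF-kB response of a protocol on a 1-min grid.
#
# The sustained component is the model's limit cycle at the protocol's
# (final) TNF level and the working temperature, phase-anchored so that a
# translocation peak occurs ~23 min after the first addition (the
# observed response latency). Each abrupt dose addition additionally
# enhances the amplitude of the first cycle peak that follows it -- the
# well-documented boosted response to an abrupt concentration increase,
# which the fixed-IKK-pool rate model does not produce on its own: a
# from-rest step simulation overshoots IkB mRNA ~5-10x its cycle range
# and goes refractory for hundreds of minutes instead. The enhancement
# multiplies N_n by 1 + phi exp(-((t - t_peak)/sigma)^2) with sigma a
# sixth of the cycle period, so only that one peak is raised; the flow
# protocol (gradual exposure, no abrupt step) gets no enhancement.
protocol_response <- function(protocol, temperature, duration, params,
                              thermal, doses,
                              peak_boost = c(1.2, 0.8), latency = 23,
                              burn_in = 3000) {
  steps <- protocol_steps(protocol, doses)
  forcing <- forcing_protocol(tnf_base = steps$level,
                              temp_base = temperature)
  traj <- simulate_nfkb(params, forcing, thermal,
                        t_end = burn_in + duration + 400, dt_out = 1,
                        transient_cut = burn_in)
  w <- trajectory_window(traj)
  amp <- diff(range(w$N_n))
  pk <- find_peaks(w$N_n, min_prominence = 0.05 * amp)
  if (!nrow(pk)) abort("protocol drive is below the oscillation onset")
  anchor <- if (length(steps$additions)) steps$additions[1] else 0
  t_shift <- w$time[pk$idx[1]] - anchor - latency
  out <- tibble(time = w$time - t_shift, N_n = w$N_n)
  out <- out[out$time >= -2 & out$time <= duration, ]
  peak_times <- w$time[pk$idx] - t_shift
  period <- attr(power_spectrum(w$N_n, 1), "peak_period")
  for (k in seq_along(steps$additions)) {
    target <- peak_times[peak_times > steps$additions[k] + 5][1]
    if (is.na(target)) next
    phi <- peak_boost[min(k, length(peak_boost))]
    out$N_n <- out$N_n *
      (1 + phi * exp(-((out$time - target) / (period / 6))^2))
  }
  out$N_n <- pmin(out$N_n, 0.97 * params$N_tot)
  out
}

#' Generate a synthetic single-cell nuclear/cytoplasmic ratio trace
#'
#' Emulates a time-lapse single-cell recording of NF-kB nuclear
#' translocation: the model is integrated at the given temperature under
#' the protocol's TNF drive (so the oscillation period carries the real
#' temperature dependence), nuclear NF-kB is mapped to an intensity
#' ratio `r = c N_n / (N_tot - N_n + b)`, and the ratio is corrupted by
#' multiplicative lognormal noise and a slow multiplicative random-walk
#' drift, then sampled every 10 minutes (the imaging interval).
#'
#' Protocols: `"single"` adds TNF (to the 10 ng/ml level) at t = -2 min;
#' `"double"` adds again (to 18 ng/ml total) at t = 38 min; `"flow"`
#' exposes the cell to the constant 1 ng/ml level throughout. Each
#' abrupt addition enhances the amplitude of the translocation peak that
#' follows it, so single-addition traces show one enhanced initial peak,
#' double-addition traces show two, and flow traces none -- see the
#' methods vignette for how this transient is constructed and why it is
#' not the raw step response of the rate model.
#'
#' @param protocol `"single"`, `"double"` or `"flow"`.
#' @param temperature working temperature, degrees C.
#' @param duration trace length, min (>= 600).
#' @param noise_sd lognormal noise sigma (relative), in \[0, 0.3\].
#' @param drift_sd total relative drift scale, in \[0, 0.3\] (the log-drift
#'   random walk accumulates to this standard deviation by the end of the
#'   trace).
#' @param seed RNG seed for the noise and drift.
#' @param params,thermal model and thermal configuration.
#' @param ratio_c,ratio_b intensity-mapping constants (ratios span roughly
#'   0.3-2 with the defaults).
#' @param doses protocol doses in ng/ml (a list with entries `single`,
#'   `double1`, `double2`, `flow`).
#' @return A tibble of class `"nfkb_trace"` with columns `time_min`,
#'   `I_N`, `I_C`, `ratio`, and attributes `protocol`, `temperature`,
#'   `true_period` (dominant period of the noiseless model trace, min),
#'   `seed`, `noise_sd`, `drift_sd`.
#' @export
generate_trace <- function(protocol = c("single", "double", "flow"),
                           temperature = 37, duration = 1440,
                           noise_sd = 0.05, drift_sd = 0.02, seed = 1,
                           params = nfkb_params(),
                           thermal = thermal_config(),
                           ratio_c = 1.0, ratio_b = 0.1,
                           doses = list(single = 10, double1 = 10,
                                        double2 = 18, flow = 1)) {
  protocol <- match.arg(protocol)
  stopifnot(duration >= 600, noise_sd >= 0, noise_sd <= 0.3,
            drift_sd >= 0, drift_sd <= 0.3)
  traj <- protocol_response(protocol, temperature, duration, params,
                            thermal, doses)
  # ground-truth period from the dense noiseless signal, past the
  # stimulation transient
  post <- traj[traj$time >= min(600, duration / 2), ]
  true_period <- attr(power_spectrum(post$N_n, dt = 1), "peak_period")

  samp <- traj[traj$time %in% seq(0, duration, by = 10), ]
  n <- nrow(samp)
  ratio0 <- ratio_c * samp$N_n / (params$N_tot - samp$N_n + ratio_b)
  set.seed(seed)
  noise <- exp(rnorm(n, 0, noise_sd))
  drift <- exp(cumsum(rnorm(n, 0, if (drift_sd > 0) drift_sd / sqrt(n) else 0)))
  ratio <- ratio0 * noise * drift
  I_C <- params$N_tot - samp$N_n + ratio_b
  out <- tibble(time_min = samp$time, I_N = ratio * I_C, I_C = I_C,
                ratio = ratio)
  structure(out, class = c("nfkb_trace", class(tibble())),
            protocol = protocol, temperature = temperature,
            true_period = true_period, seed = seed,
            noise_sd = noise_sd, drift_sd = drift_sd)
}

# deterministic per-cell mapping-constant jitter for a cohort
cohort_cell_params <- function(seed, n_cells, ratio_c = 1.0, ratio_b = 0.1,
                               jitter = 0.1) {
  set.seed(seed)
  tibble(
    cell = seq_len(n_cells),
    seed = vapply(seq_len(n_cells), function(i) child_seed(seed, i),
                  integer(1)),
    ratio_c = ratio_c * (1 + runif(n_cells, -jitter, jitter)),
    ratio_b = ratio_b * (1 + runif(n_cells, -jitter, jitter))
  )
}

#' Generate a cohort of synthetic single-cell traces
#'
#' Independent traces sharing protocol and temperature, with per-cell
#' intensity-mapping constants jittered by +/-10% and per-cell noise
#' seeds derived deterministically from the cohort seed.
#'
#' @param n_cells number of cells (>= 1).
#' @inheritParams generate_trace
#' @param jitter relative jitter of the mapping constants.
#' @param ... passed to [generate_trace()] (e.g. `duration`, `noise_sd`).
#' @return A list of class `"nfkb_cohort"` with elements `traces` (list of
#'   `nfkb_trace`) and `manifest` (tibble: cell, seed, ratio_c, ratio_b,
#'   true_period_min, protocol, temperature).
#' @export
generate_cohort <- function(n_cells, protocol = c("single", "double", "flow"),
                            temperature = 37, seed = 1, jitter = 0.1, ...) {
  stopifnot(n_cells >= 1)
  protocol <- match.arg(protocol)
  cells <- cohort_cell_params(seed, n_cells, jitter = jitter)
  traces <- purrr::pmap(cells, function(cell, seed, ratio_c, ratio_b) {
    generate_trace(protocol, temperature, seed = seed,
                   ratio_c = ratio_c, ratio_b = ratio_b, ...)
  })
  manifest <- dplyr::mutate(
    cells,
    true_period_min = purrr::map_dbl(traces, ~ attr(.x, "true_period")),
    protocol = protocol, temperature = temperature
  )
  structure(list(traces = traces, manifest = manifest),
            class = "nfkb_cohort")
}

#' @export
print.nfkb_cohort <- function(x, ...) {
  cat(sprintf("<nfkb_cohort> %d cells, protocol '%s', %.1f degC\n",
              length(x$traces), x$manifest$protocol[1],
              x$manifest$temperature[1]))
  invisible(x)
}

#' Write a cohort of traces to per-cell CSV files
#'
#' One `cell_<i>.csv` per cell (header `time_min,I_N,I_C,ratio`) plus a
#' `manifest.json` with the seeds, mapping constants and ground-truth
#' periods.
#'
#' @param cohort an [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_traces <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nfkb_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(cohort$traces)) {
    readr::write_csv(as_tibble(cohort$traces[[i]]),
                     file.path(dir, sprintf("cell_%03d.csv", i)))
  }
  jsonlite::write_json(cohort$manifest,
                       file.path(dir, "manifest.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Read a single-cell trace from delimited text
#'
#' Accepts either `time_min,I_N,I_C` (the ratio is computed) or
#' `time_min,ratio`.
#'
#' @param path CSV file path.
#' @return A tibble of class `"nfkb_trace"`.
#' @export
read_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (all(c("time_min", "I_N", "I_C") %in% names(df))) {
    df$ratio <- df$I_N / df$I_C
  } else if (!all(c("time_min", "ratio") %in% names(df))) {
    abort("trace file needs columns time_min,I_N,I_C or time_min,ratio")
  }
  structure(as_tibble(df), class = c("nfkb_trace", class(tibble())))
}
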
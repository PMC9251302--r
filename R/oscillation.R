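#' Peak-to-trough oscillation amplitude of nuclear NF-kB
#'
#' Range of `N_n` over the post-transient window. When the trajectory
#' oscillates, the window is required to cover at least five nominal
#' periods (estimated from the spectral peak) so the range samples the
#' full cycle.
#'
#' @param traj an `nfkb_trajectory`.
#' @param check_window verify the five-period precondition (default TRUE).
#' @return Amplitude in uM (0 for a trajectory at a fixed point).
#' @export
oscillation_amplitude <- function(traj, check_window = TRUE) {
  w <- trajectory_window(traj)
  amp <- diff(range(w$N_n))
  if (check_window && amp > 1e-6) {
    per <- attr(power_spectrum(w$N_n, dt = w$time[2] - w$time[1]), "peak_period")
    horizon <- diff(range(w$time))
    if (horizon < 5 * per) {
      abort(sprintf("post-transient window (%.0f min) shorter than 5 periods (%.0f min)",
                    horizon, 5 * per))
    }
  }
  amp
}

#' Time-averaged absolute rate of change of nuclear NF-kB
#'
#' Mean of |dN_n/dt| over the post-transient window, with the derivative
#' evaluated from the model right-hand side along the stored trajectory
#' (not by finite differences). This quantity is near zero at a stable
#' fixed point and rises sharply at the onset of oscillations, so its
#' profile against TNF locates the Hopf bifurcation.
#'
#' @param traj an `nfkb_trajectory`.
#' @return Mean |dN_n/dt| in uM/min.
#' @export
mean_abs_derivative <- function(traj) {
  w <- trajectory_window(traj)
  d <- trajectory_derivatives(w)
  mean(abs(d$dN_n))
}

#' TNF level at the onset of oscillations (Hopf threshold)
#'
#' Locates, by bisection on constant TNF, the threshold above which the
#' model oscillates at the given temperature. The criterion is a
#' post-transient peak-to-trough amplitude of nuclear NF-kB exceeding
#' `amp_criterion`; the bracket endpoints must straddle it.
#'
#' @param T_celsius working temperature, degrees C.
#' @param params,thermal model and thermal configuration.
#' @param bracket TNF interval known to straddle the bifurcation.
#' @param tol bisection resolution in TNF (default 1e-4); the midpoint of
#'   the final bracket is returned.
#' @param amp_criterion oscillation amplitude threshold in uM.
#' @param t_end,transient_cut,dt_out simulation controls per evaluation.
#'   Near the onset the fixed point is only weakly damped, so besides
#'   exceeding `amp_criterion` the amplitude must also be sustained: it
#'   is measured over the two halves of the post-transient window and a
#'   decaying second half (< 80% of the first) marks slowly damped
#'   ringing, not a limit cycle.
#' @return The threshold TNF level (dimensionless).
#' @export
hopf_threshold <- function(T_celsius, params = nfkb_params(),
                           thermal = thermal_config(),
                           bracket = c(1e-3, 1), tol = 1e-4,
                           amp_criterion = 1e-4,
                           t_end = 30000, transient_cut = 10000, dt_out = 1) {
  oscillating_at <- function(tnf) {
    traj <- simulate_nfkb(params,
                          forcing_protocol(tnf_base = tnf, temp_base = T_celsius),
                          thermal, t_end = t_end, dt_out = dt_out,
                          transient_cut = transient_cut)
    w <- trajectory_window(traj)
    half <- nrow(w) %/% 2
    # peak prominence separates oscillation from slow monotone drift
    p1 <- find_peaks(w$N_n[seq_len(half)])$prominence
    p2 <- find_peaks(w$N_n[(half + 1):nrow(w)])$prominence
    p1 <- if (length(p1)) max(p1) else 0
    p2 <- if (length(p2)) max(p2) else 0
    p2 > amp_criterion && p2 > 0.8 * p1
  }
  lo <- bracket[1]; hi <- bracket[2]
  osc_lo <- oscillating_at(lo)
  osc_hi <- oscillating_at(hi)
  if (osc_lo == osc_hi) {
    abort(sprintf(
      "bracket does not straddle the bifurcation: TNF = %.3g is %s and TNF = %.3g is %s",
      lo, if (osc_lo) "oscillating" else "quiescent",
      hi, if (osc_hi) "oscillating" else "quiescent"))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (oscillating_at(mid) == osc_hi) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Period, amplitude and mean |dN/dt| across a temperature grid
#'
#' One simulation per (temperature, TNF) pair, with the dominant spectral
#' period extracted where the trajectory oscillates; non-oscillating grid
#' points are flagged and carry `NA` periods.
#'
#' @param temperatures grid of working temperatures, degrees C.
#' @param tnf_levels constant TNF levels to sweep.
#' @param params,thermal model and thermal configuration.
#' @param t_end,transient_cut,dt_out simulation controls.
#' @param amp_criterion amplitude above which a point counts as
#'   oscillating (uM).
#' @return A tibble of class `"nfkb_sweep"`: `temperature_C`, `tnf`,
#'   `period_min`, `amplitude_uM`, `mean_abs_dNdt`, `oscillating`.
#' @seealso [fit_period_slope()]
#' @export
sweep_period_temperature <- function(temperatures = seq(32, 39.5, by = 0.5),
                                     tnf_levels = c(0.2, 0.5, 1.0),
                                     params = nfkb_params(),
                                     thermal = thermal_config(),
                                     t_end = 10000, transient_cut = 2000,
                                     dt_out = 1, amp_criterion = 1e-4) {
  grid <- tidyr::expand_grid(temperature_C = temperatures, tnf = tnf_levels)
  rows <- purrr::pmap(grid, function(temperature_C, tnf) {
    traj <- simulate_nfkb(params,
                          forcing_protocol(tnf_base = tnf,
                                           temp_base = temperature_C),
                          thermal, t_end = t_end, dt_out = dt_out,
                          transient_cut = transient_cut)
    amp <- oscillation_amplitude(traj, check_window = FALSE)
    osc <- amp > amp_criterion
    tibble(
      temperature_C = temperature_C, tnf = tnf,
      period_min = if (osc) dominant_period(traj) else NA_real_,
      amplitude_uM = amp,
      mean_abs_dNdt = mean_abs_derivative(traj),
      oscillating = osc
    )
  })
  structure(dplyr::bind_rows(rows),
            class = c("nfkb_sweep", class(tibble())))
}

#' Least-squares slope of oscillation period against temperature
#'
#' Fits `period ~ temperature` by ordinary least squares over the
#' oscillating points of a sweep at one TNF level, within a temperature
#' range. The range default (32-39.5 degrees C) matches the span over
#' which single-cell experiments resolve oscillations at every protocol.
#'
#' @param sweep an [sweep_period_temperature()] result.
#' @param tnf which TNF level of the sweep to fit.
#' @param t_range inclusive temperature range used in the fit.
#' @return An object of class `"period_slope_fit"` wrapping the `lm` fit;
#'   see [tidy()] and [glance()] methods.
#' @export
fit_period_slope <- function(sweep, tnf = 0.5, t_range = c(32, 39.5)) {
  stopifnot(inherits(sweep, "nfkb_sweep"))
  dat <- dplyr::filter(sweep, .data$tnf == !!tnf, .data$oscillating,
                       .data$temperature_C >= t_range[1],
                       .data$temperature_C <= t_range[2])
  if (nrow(dat) < 3L) abort("need at least 3 oscillating grid points to fit")
  fit <- lm(period_min ~ temperature_C, data = dat)
  structure(list(fit = fit, tnf = tnf, t_range = t_range,
                 n_points = nrow(dat), n_excluded = sum(!sweep$oscillating &
                                                          sweep$tnf == tnf)),
            class = "period_slope_fit")
}

#' @export
print.period_slope_fit <- function(x, ...) {
  cat(sprintf("<period_slope_fit> TNF = %.3g, %d points in [%.1f, %.1f] degC\n",
              x$tnf, x$n_points, x$t_range[1], x$t_range[2]))
  cat(sprintf("  slope: %.2f min/degC\n", coef(x$fit)[2]))
  invisible(x)
}

#' @rdname fit_period_slope
#' @param x a `period_slope_fit`.
#' @param ... unused.
#' @export
tidy.period_slope_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname fit_period_slope
#' @export
glance.period_slope_fit <- function(x, ...) {
  tibble(
    slope_min_per_C = unname(coef(x$fit)[2]),
    intercept_min = unname(coef(x$fit)[1]),
    r.squared = summary(x$fit)$r.squared,
    tnf = x$tnf, n_points = x$n_points, n_excluded = x$n_excluded
  )
}
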
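#' Power spectrum and dominant period of a uniformly sampled signal
#'
#' Mean-subtracted discrete-Fourier power spectrum with a rectangular
#' window, zero-padded to the next power of two at least four times the
#' sample count for fine peak localisation. The dominant frequency is the
#' maximal non-DC power bin, refined by parabolic interpolation over the
#' peak and its two neighbours. Oscillations of the relaxation type carry
#' harmonics of the fundamental; the maximal bin is normally the
#' fundamental, and `peak_is_lowest` records whether it is also the lowest
#' substantial spectral peak.
#'
#' @param x a numeric signal (uniform sampling) or an `nfkb_trajectory`,
#'   in which case the post-transient `N_n` series is analysed.
#' @param dt sample spacing in minutes (ignored for trajectories).
#' @param ... unused.
#' @return An object of class `"nfkb_spectrum"`: a tibble with columns
#'   `frequency` (1/min) and `power`, and attributes `peak_frequency`,
#'   `peak_period`, `peak_power`, `freq_resolution` (the unpadded bin
#'   width 1/(n dt)) and `peak_is_lowest`.
#' @examples
#' t <- seq(0, 4095)
#' sp <- power_spectrum(sin(2 * pi * t / 90), dt = 1)
#' glance(sp)
#' @export
power_spectrum <- function(x, dt = 1, ...) UseMethod("power_spectrum")

#' @export
power_spectrum.nfkb_trajectory <- function(x, dt = 1, ...) {
  w <- trajectory_window(x)
  power_spectrum(w$N_n, dt = w$time[2] - w$time[1])
}

#' @export
power_spectrum.numeric <- function(x, dt = 1, ...) {
  n <- length(x)
  if (n < 64L) abort("need at least 64 samples for a spectrum")
  stopifnot(dt > 0)
  x <- x - mean(x)
  if (stats::var(x) < 1e-18) abort("flat signal: no spectral peak")
  nfft <- 2^ceiling(log2(max(4 * n, 64)))
  p <- Mod(fft(c(x, rep(0, nfft - n))))^2
  half <- seq_len(nfft %/% 2 + 1L)          # DC .. Nyquist
  freq <- (half - 1L) / (nfft * dt)
  pow <- p[half]
  k <- which.max(pow[-1L]) + 1L             # exclude the DC bin
  off <- if (k > 2L && k < length(pow)) {
    parabolic_offset(pow[k - 1L], pow[k], pow[k + 1L])
  } else 0
  peak_f <- (k - 1L + off) / (nfft * dt)
  # is the maximal bin also the lowest substantial spectral peak, or does
  # a stronger-than-5% peak sit well below it (a subharmonic)?
  pk <- find_peaks(pow[-1L], min_prominence = 0.05 * pow[k])
  pk_freq <- (pk$idx) / (nfft * dt)          # idx is offset by the DC bin
  structure(
    tibble(frequency = freq, power = pow),
    class = c("nfkb_spectrum", class(tibble())),
    peak_frequency = peak_f,
    peak_period = 1 / peak_f,
    peak_power = pow[k],
    freq_resolution = 1 / (n * dt),
    peak_is_lowest = !any(pk_freq < 0.8 * peak_f)
  )
}

#' @export
glance.nfkb_spectrum <- function(x, ...) {
  tibble(
    peak_frequency = attr(x, "peak_frequency"),
    peak_period = attr(x, "peak_period"),
    peak_power = attr(x, "peak_power"),
    freq_resolution = attr(x, "freq_resolution"),
    peak_is_lowest = attr(x, "peak_is_lowest")
  )
}

#' Dominant oscillation period of a trajectory
#'
#' @param traj an `nfkb_trajectory`.
#' @return Period in minutes (from the spectral peak of post-transient
#'   nuclear NF-kB).
#' @export
dominant_period <- function(traj) {
  attr(power_spectrum(traj), "peak_period")
}

#' Mean interval between successive nuclear NF-kB peaks
#'
#' An estimator of the oscillation period independent of the spectral
#' route: local maxima of post-transient `N_n` with prominence at least 5%
#' of the peak-to-trough range, averaged inter-peak spacing.
#'
#' @param traj an `nfkb_trajectory`.
#' @return Mean inter-peak interval in minutes (NA with < 3 peaks).
#' @export
mean_peak_interval <- function(traj) {
  w <- trajectory_window(traj)
  rng <- diff(range(w$N_n))
  pk <- find_peaks(w$N_n, min_prominence = 0.05 * rng)
  if (nrow(pk) < 3L) return(NA_real_)
  mean(diff(w$time[pk$idx]))
}
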
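#' Centered moving average with shrinking end windows
#'
#' The smoothing convention of the classic MATLAB `smooth` function: an
#' even `span` is reduced by one so the window is always odd and
#' centered, and near the series ends the window shrinks symmetrically
#' (sizes 1, 3, 5, ...) so the output has the same length as the input.
#' A linear ramp is therefore reproduced exactly, ends included.
#'
#' @param x numeric series.
#' @param span nominal window size (>= 1, < `length(x)`).
#' @return The smoothed series, same length as `x`.
#' @examples
#' moving_average(c(1, 2, 3, 4, 5), span = 3)
#' @export
moving_average <- function(x, span) {
  n <- length(x)
  stopifnot(span >= 1)
  if (span >= n) abort("span must be smaller than the series length")
  if (span %% 2 == 0) span <- span - 1L
  h <- (span - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)
    mean(x[(i - hi):(i + hi)])
  }, numeric(1))
}

#' Detrend an intensity-ratio series
#'
#' Difference of two moving averages: the span-4 smoother keeps the
#' oscillation while suppressing sample-to-sample noise, and the span-13
#' smoother tracks (and thereby removes) intensity variations slower than
#' the oscillation period. Linear: `detrend(a x + b y) =
#' a detrend(x) + b detrend(y)`; a constant or linear-in-time series maps
#' to zero away from the edges.
#'
#' @param x numeric series, length > 13.
#' @param span_fast,span_slow the two smoothing spans.
#' @return The detrended series.
#' @export
detrend_trace <- function(x, span_fast = 4, span_slow = 13) {
  if (length(x) <= span_slow) {
    abort(sprintf("series must be longer than %d samples", span_slow))
  }
  moving_average(x, span_fast) - moving_average(x, span_slow)
}

#' Extract the dominant period of an intensity-ratio trace
#'
#' Power-spectral analysis of the mean-subtracted ratio series
#' (zero-padded to at least 4096 points): the highest non-DC peak gives
#' the period. When `override_band` is supplied, the highest peak inside
#' that frequency band is taken instead (`used_override` is set) -- the
#' reproducible equivalent of manually choosing the peak near the
#' visually observed oscillation when a spurious low- or high-frequency
#' component dominates. A peak below three times the median spectral
#' power counts as noise and yields a no-period result rather than an
#' error.
#'
#' @param trace an `nfkb_trace` (or data frame with `time_min` and
#'   `ratio` columns) with at least 9 samples.
#' @param override_band optional `c(f_lo, f_hi)` frequency band, 1/min.
#' @param plausible_range period band (min) outside which the estimate is
#'   flagged as implausible.
#' @return A one-row tibble of class `"period_estimate"`: `period_min`,
#'   `frequency_per_min`, `power_at_peak`, `used_override`, `no_period`,
#'   `plausible`, `freq_resolution` (the unpadded bin width, reported as
#'   the estimate's uncertainty).
#' @export
extract_period <- function(trace, override_band = NULL,
                           plausible_range = c(20, 600)) {
  df <- as.data.frame(trace)
  if (!all(c("time_min", "ratio") %in% names(df))) {
    abort("trace needs columns time_min and ratio")
  }
  n <- nrow(df)
  if (n < 9L) abort("trace must have at least 9 samples")
  dt <- df$time_min[2] - df$time_min[1]
  if (any(abs(diff(df$time_min) - dt) > 1e-6)) {
    abort("trace must be uniformly sampled")
  }
  x <- df$ratio - mean(df$ratio)
  nfft <- 2^ceiling(log2(max(4096, 4 * n)))
  p <- Mod(fft(c(x, rep(0, nfft - n))))^2
  half <- 2:(nfft %/% 2 + 1L)
  freq <- (half - 1L) / (nfft * dt)
  pow <- p[half]
  noise_floor <- 3 * median(pow)
  in_band <- if (is.null(override_band)) rep(TRUE, length(freq)) else
    freq >= override_band[1] & freq <= override_band[2]
  if (!any(in_band)) abort("override_band contains no frequency bins")
  k <- which(in_band)[which.max(pow[in_band])]
  no_period <- pow[k] < noise_floor
  if (no_period) {
    out <- tibble(period_min = NA_real_, frequency_per_min = NA_real_,
                  power_at_peak = pow[k],
                  used_override = !is.null(override_band),
                  no_period = TRUE, plausible = NA,
                  freq_resolution = 1 / (n * dt))
    return(structure(out, class = c("period_estimate", class(tibble()))))
  }
  off <- if (k > 1L && k < length(pow)) {
    parabolic_offset(pow[k - 1L], pow[k], pow[k + 1L])
  } else 0
  f <- (k + off) / (nfft * dt)
  period <- 1 / f
  out <- tibble(
    period_min = period, frequency_per_min = f, power_at_peak = pow[k],
    used_override = !is.null(override_band), no_period = FALSE,
    plausible = period >= plausible_range[1] & period <= plausible_range[2],
    freq_resolution = 1 / (n * dt)
  )
  structure(out, class = c("period_estimate", class(tibble())))
}

#' Period statistics over a cohort of traces
#'
#' Runs [extract_period()] on every trace and reports the arithmetic mean
#' and sample standard deviation of the recovered periods; traces with no
#' spectral peak above the noise floor are excluded and counted.
#'
#' @param cohort an `nfkb_cohort`, or a list of traces.
#' @param ... passed to [extract_period()] (e.g. `override_band`).
#' @return A one-row tibble `mean_period_min`, `sd_period_min`, `n`,
#'   `n_excluded`; per-cell estimates in attribute `"periods"`.
#' @export
cohort_period_stats <- function(cohort, ...) {
  traces <- if (inherits(cohort, "nfkb_cohort")) cohort$traces else cohort
  per <- purrr::map_dfr(seq_along(traces), function(i) {
    dplyr::mutate(extract_period(traces[[i]], ...), cell = i,
                  .before = 1)
  })
  ok <- !per$no_period
  if (sum(ok) < 2L) abort("need at least 2 traces with a detectable period")
  out <- tibble(
    mean_period_min = mean(per$period_min[ok]),
    sd_period_min = sd(per$period_min[ok]),
    n = sum(ok), n_excluded = sum(!ok)
  )
  attr(out, "periods") <- per
  out
}

#' Two-sample t test on the periods of two cohorts
#'
#' Convenience wrapper around Welch's two-sample t test comparing the
#' per-cell period estimates of two cohorts (standard statistics, no
#' model content).
#'
#' @param a,b cohorts or trace lists.
#' @param ... passed to [extract_period()].
#' @return A tibble with the t statistic, degrees of freedom, p value and
#'   the two cohort means.
#' @export
compare_cohort_periods <- function(a, b, ...) {
  pa <- attr(cohort_period_stats(a, ...), "periods")
  pb <- attr(cohort_period_stats(b, ...), "periods")
  tt <- stats::t.test(pa$period_min[!pa$no_period],
                      pb$period_min[!pb$no_period])
  tibble(statistic = unname(tt$statistic),
         parameter = unname(tt$parameter),
         p.value = tt$p.value,
         mean_a = unname(tt$estimate[1]), mean_b = unname(tt$estimate[2]))
}
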
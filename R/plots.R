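#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_step labs
#'   facet_wrap scale_y_log10 theme_minimal
NULL

#' Plot a simulated trajectory
#'
#' @param object an `nfkb_trajectory`.
#' @param vars state variables to show.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.nfkb_trajectory <- function(object, vars = "N_n", ...) {
  df <- tidyr::pivot_longer(as_tibble(object)[c("time", vars)],
                            -"time", names_to = "variable")
  ggplot(df, aes(.data$time, .data$value, colour = .data$variable)) +
    geom_line() +
    labs(x = "time (min)", y = "concentration (uM)", colour = NULL) +
    theme_minimal()
}

#' Plot a power spectrum
#'
#' @param object an `nfkb_spectrum`.
#' @param ... unused.
#' @return A ggplot (log power against frequency).
#' @export
autoplot.nfkb_spectrum <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$frequency > 0 & df$power > 0, ]
  ggplot(df, aes(.data$frequency, .data$power)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "frequency (1/min)", y = "power") +
    theme_minimal()
}

#' Plot a period-versus-temperature sweep
#'
#' @param object an `nfkb_sweep`.
#' @param ... unused.
#' @return A ggplot, one curve per TNF level.
#' @export
autoplot.nfkb_sweep <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$oscillating)
  ggplot(df, aes(.data$temperature_C, .data$period_min,
                 colour = factor(.data$tnf))) +
    geom_line() + geom_point() +
    labs(x = "temperature (degC)", y = "period (min)", colour = "TNF") +
    theme_minimal()
}

#' Plot a Devil's staircase
#'
#' @param object an `nfkb_staircase`.
#' @param ... unused.
#' @return A ggplot of rotation number against forcing frequency, with
#'   locked points highlighted.
#' @export
autoplot.nfkb_staircase <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(.data$f_tmp, .data$W_refined)) +
    geom_step() +
    geom_point(aes(colour = !is.na(.data$locked_ratio))) +
    labs(x = "forcing frequency (1/min)", y = "rotation number W",
         colour = "locked") +
    theme_minimal()
}

#' Plot the twin-trajectory distance of a divergence run
#'
#' @param object an `nfkb_divergence`.
#' @param ... unused.
#' @return A ggplot of distance against time (log scale).
#' @export
autoplot.nfkb_divergence <- function(object, ...) {
  df <- attr(object, "distance")
  df <- df[df$distance > 0, ]
  ggplot(df, aes(.data$time, .data$distance)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "time (min)", y = "phase-space distance (uM)") +
    theme_minimal()
}

#' Plot a synthetic or imported intensity-ratio trace
#'
#' @param object an `nfkb_trace`.
#' @param detrended overlay the smoothed/detrended series.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.nfkb_trace <- function(object, detrended = FALSE, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(.data$time_min, .data$ratio)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "time (min)", y = "I_N / I_C") +
    theme_minimal()
  if (detrended) {
    df$detrended <- detrend_trace(df$ratio)
    p <- p + geom_line(data = df, aes(y = .data$detrended),
                       colour = "steelblue")
  }
  p
}
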
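#' Forcing protocol: TNF drive and external temperature
#'
#' Describes the two external inputs of a simulation. TNF (dimensionless,
#' 0-1 scale) can be held constant, oscillated sinusoidally
#' `TNF(t) = tnf_base + tnf_amplitude * sin(2 pi t / tnf_period)` (clamped
#' at zero from below), or follow a piecewise-constant step sequence
#' emulating ligand-addition protocols. Temperature (degrees C) is either
#' constant or a sinusoid
#' `T(t) = temp_base + temp_amplitude * sin(2 pi temp_frequency t)`;
#' physiological temperatures are never clamped.
#'
#' @param tnf_mode one of `"constant"`, `"sinusoid"`, `"steps"`.
#' @param tnf_base baseline TNF level (the sinusoid oscillates around it and
#'   a step sequence starts from it).
#' @param tnf_amplitude sinusoid amplitude (dimensionless).
#' @param tnf_period sinusoid period in minutes.
#' @param tnf_steps for `"steps"`: a data frame / tibble with columns `time`
#'   (min) and `level`; TNF holds `tnf_base` before the first step and the
#'   most recent level afterwards.
#' @param temp_mode `"constant"` or `"sinusoid"`.
#' @param temp_base baseline temperature in degrees C.
#' @param temp_amplitude temperature oscillation amplitude in degrees C.
#' @param temp_frequency temperature oscillation frequency in 1/min.
#' @return An object of class `"forcing_protocol"`.
#' @examples
#' forcing_protocol(tnf_base = 0.5, temp_base = 37)
#' forcing_protocol(temp_mode = "sinusoid", temp_amplitude = 1,
#'                  temp_frequency = 0.01)
#' forcing_protocol(tnf_mode = "steps", tnf_base = 0,
#'                  tnf_steps = data.frame(time = -2, level = 0.5))
#' @export
forcing_protocol <- function(tnf_mode = c("constant", "sinusoid", "steps"),
                             tnf_base = 0.5, tnf_amplitude = 0,
                             tnf_period = 100, tnf_steps = NULL,
                             temp_mode = c("constant", "sinusoid"),
                             temp_base = 37, temp_amplitude = 0,
                             temp_frequency = 0) {
  tnf_mode <- match.arg(tnf_mode)
  temp_mode <- match.arg(temp_mode)
  if (tnf_mode == "sinusoid" && tnf_period <= 0) abort("tnf_period must be > 0")
  if (temp_mode == "sinusoid" && temp_frequency <= 0) {
    abort("temp_frequency must be > 0 for sinusoidal temperature")
  }
  if (tnf_mode == "steps") {
    if (is.null(tnf_steps) || !all(c("time", "level") %in% names(tnf_steps))) {
      abort("tnf_steps must be a data frame with columns time and level")
    }
    tnf_steps <- as_tibble(tnf_steps)[c("time", "level")]
    if (nrow(tnf_steps) < 1L || nrow(tnf_steps) > 32L) {
      abort("between 1 and 32 TNF steps are supported")
    }
    if (is.unsorted(tnf_steps$time, strictly = TRUE)) {
      abort("tnf_steps times must be strictly increasing")
    }
    if (any(tnf_steps$level < 0)) abort("TNF step levels must be >= 0")
  }
  if (tnf_base < 0) abort("tnf_base must be >= 0")
  structure(list(
    tnf_mode = tnf_mode, tnf_base = tnf_base, tnf_amplitude = tnf_amplitude,
    tnf_period = tnf_period, tnf_steps = tnf_steps,
    temp_mode = temp_mode, temp_base = temp_base,
    temp_amplitude = temp_amplitude, temp_frequency = temp_frequency
  ), class = "forcing_protocol")
}

#' Evaluate the TNF drive of a protocol
#'
#' @param forcing a [forcing_protocol()].
#' @param t time(s) in minutes.
#' @return TNF level(s), clamped at >= 0.
#' @export
tnf_at <- function(forcing, t) {
  out <- switch(forcing$tnf_mode,
    constant = rep(forcing$tnf_base, length(t)),
    sinusoid = forcing$tnf_base +
      forcing$tnf_amplitude * sin(2 * pi * t / forcing$tnf_period),
    steps = {
      idx <- findInterval(t, forcing$tnf_steps$time)
      ifelse(idx == 0, forcing$tnf_base, forcing$tnf_steps$level[pmax(idx, 1)])
    }
  )
  pmax(out, 0)
}

#' Evaluate the temperature signal of a protocol
#'
#' @inheritParams tnf_at
#' @return Temperature(s) in degrees C (not clamped).
#' @export
temperature_at <- function(forcing, t) {
  if (forcing$temp_mode == "sinusoid") {
    forcing$temp_base +
      forcing$temp_amplitude * sin(2 * pi * forcing$temp_frequency * t)
  } else {
    rep(forcing$temp_base, length(t))
  }
}

#' @export
print.forcing_protocol <- function(x, ...) {
  cat("<forcing_protocol>\n")
  if (x$tnf_mode == "constant") {
    cat(sprintf("  TNF: constant %.3g\n", x$tnf_base))
  } else if (x$tnf_mode == "sinusoid") {
    cat(sprintf("  TNF: %.3g + %.3g sin(2 pi t / %.3g)\n",
                x$tnf_base, x$tnf_amplitude, x$tnf_period))
  } else {
    cat(sprintf("  TNF: steps from %.3g at t = %s min\n", x$tnf_base,
                paste(x$tnf_steps$time, collapse = ", ")))
  }
  if (x$temp_mode == "constant") {
    cat(sprintf("  temperature: constant %.2f degC\n", x$temp_base))
  } else {
    cat(sprintf("  temperature: %.2f + %.2f sin(2 pi %.4g t) degC\n",
                x$temp_base, x$temp_amplitude, x$temp_frequency))
  }
  invisible(x)
}
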
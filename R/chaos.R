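#' Twin-trajectory divergence under temperature forcing
#'
#' Diagnoses chaos by sensitivity to initial conditions: a reference
#' trajectory is integrated past the transient, a companion is started
#' from the same state with every component multiplied by
#' `1 + epsilon_rel`, and both are integrated over `horizon` minutes. The
#' result is the mean Euclidean distance between them in `(N_n, I_m, I)`
#' space, compared against the attractor diameter (the diagonal of the
#' reference orbit's bounding box). On a regular attractor the twins
#' re-converge (up to phase) and the mean distance stays far below the
#' attractor scale; on a strange attractor it grows to the attractor
#' scale. `is_chaotic` is TRUE when the mean distance exceeds
#' `chaos_fraction` of the diameter.
#'
#' @param A_T forcing amplitude, degrees C.
#' @param f_tmp forcing frequency, 1/min.
#' @param tnf constant TNF level.
#' @param epsilon_rel relative initial separation, in (0, 1e-3]; 0 is
#'   allowed as a control and gives bit-identical twins.
#' @param seed optional: draw the pre-transient initial state with this
#'   seed; default uses [default_init()].
#' @param temp_base mean temperature, degrees C.
#' @param params,thermal model and thermal configuration.
#' @param transient discarded transient, min.
#' @param horizon compared horizon, min.
#' @param dt_out sampling of the compared window, min.
#' @param chaos_fraction threshold on `mean_distance / attractor_diameter`.
#' @return A one-row tibble of class `"nfkb_divergence"`: `A_T`, `f_tmp`,
#'   `tnf`, `epsilon_rel`, `mean_distance`, `attractor_diameter`,
#'   `distance_ratio`, `is_chaotic`; the distance time series is in
#'   attribute `"distance"`.
#' @export
divergence_metric <- function(A_T, f_tmp, tnf = 0.5, epsilon_rel = 1e-6,
                              seed = NULL, temp_base = 37,
                              params = nfkb_params(),
                              thermal = thermal_config(),
                              transient = 2000, horizon = 5000, dt_out = 1,
                              chaos_fraction = 0.1) {
  stopifnot(epsilon_rel >= 0, epsilon_rel <= 1e-3)
  forcing <- forcing_protocol(tnf_base = tnf, temp_base = temp_base,
                              temp_mode = if (A_T > 0) "sinusoid" else "constant",
                              temp_amplitude = A_T, temp_frequency = f_tmp)
  init <- if (is.null(seed)) default_init() else
    random_initial_state(seed, params)
  pre <- simulate_nfkb(params, forcing, thermal, t_end = transient,
                       dt_out = transient / 4, transient_cut = 0,
                       init = init)
  y0 <- unlist(pre[nrow(pre), .state_names])
  run <- function(y) {
    simulate_nfkb(params, forcing, thermal, t_start = transient,
                  t_end = transient + horizon, dt_out = dt_out,
                  transient_cut = 0, init = y)
  }
  a <- run(y0)
  b <- run(y0 * (1 + epsilon_rel))
  dd <- sqrt((a$N_n - b$N_n)^2 + (a$I_m - b$I_m)^2 + (a$I - b$I)^2)
  ref <- as.matrix(a[, c("N_n", "I_m", "I")])
  diam <- sqrt(sum((apply(ref, 2, max) - apply(ref, 2, min))^2))
  out <- tibble(
    A_T = A_T, f_tmp = f_tmp, tnf = tnf, epsilon_rel = epsilon_rel,
    mean_distance = mean(dd), attractor_diameter = diam,
    distance_ratio = mean(dd) / diam,
    is_chaotic = mean(dd) > chaos_fraction * diam
  )
  structure(out, class = c("nfkb_divergence", class(tibble())),
            distance = tibble(time = a$time, distance = dd))
}

#' Smallest forcing amplitude with chaotic dynamics
#'
#' Scans temperature-oscillation amplitudes in increasing order; at each
#' amplitude the divergence criterion is evaluated from `n_seeds` random
#' initial conditions and the amplitude counts as chaotic when the
#' majority are. The first chaotic grid amplitude is then refined by
#' bisection (same majority rule) against the last non-chaotic one, to
#' resolution `refine_tol`.
#'
#' @param f_tmp forcing frequency, 1/min.
#' @param tnf constant TNF level.
#' @param a_grid increasing amplitudes scanned, degrees C.
#' @param n_seeds initial conditions per amplitude (majority vote).
#' @param seed base seed for the draws.
#' @param refine_tol bisection resolution, degrees C.
#' @param ... passed to [divergence_metric()].
#' @return A one-row tibble `f_tmp`, `tnf`, `transition_amplitude`
#'   (NA when no grid amplitude is chaotic), `found`; the grid votes are
#'   in attribute `"scan"`.
#' @export
chaos_transition_amplitude <- function(f_tmp, tnf = 0.5,
                                       a_grid = seq(0, 5, by = 0.25),
                                       n_seeds = 3, seed = 1,
                                       refine_tol = 0.05, ...) {
  if (is.unsorted(a_grid)) abort("a_grid must be increasing")
  majority <- function(a) {
    votes <- purrr::map_lgl(seq_len(n_seeds), function(s) {
      divergence_metric(A_T = a, f_tmp = f_tmp, tnf = tnf,
                        seed = child_seed(seed, s), ...)$is_chaotic
    })
    mean(votes) > 0.5
  }
  votes <- logical(0)
  first_chaotic <- NA_real_
  last_regular <- NA_real_
  for (a in a_grid) {
    ch <- majority(a)
    votes <- c(votes, ch)
    if (ch) {
      first_chaotic <- a
      break
    }
    last_regular <- a
  }
  scan <- tibble(A_T = a_grid[seq_along(votes)], chaotic = votes)
  if (is.na(first_chaotic)) {
    out <- tibble(f_tmp = f_tmp, tnf = tnf,
                  transition_amplitude = NA_real_, found = FALSE)
    attr(out, "scan") <- scan
    return(out)
  }
  lo <- if (is.na(last_regular)) 0 else last_regular
  hi <- first_chaotic
  while (hi - lo > refine_tol) {
    mid <- (lo + hi) / 2
    if (majority(mid)) hi <- mid else lo <- mid
  }
  out <- tibble(f_tmp = f_tmp, tnf = tnf, transition_amplitude = hi,
                found = TRUE)
  attr(out, "scan") <- scan
  out
}

#' Largest Lyapunov exponent by two-trajectory renormalisation
#'
#' Benettin-style estimate: a companion trajectory is kept at separation
#' `d0` from the reference (in the full five-dimensional state space) and
#' renormalised back to `d0` along the current separation direction every
#' `tau` minutes; the exponent is the average logarithmic stretching rate
#' `sum(log(d_i/d0)) / (n tau)`. Positive values diagnose chaos; regular
#' (periodic or quasiperiodic) forcing gives values at or below zero up
#' to O(1/horizon) estimation noise.
#'
#' @param A_T forcing amplitude, degrees C.
#' @param f_tmp forcing frequency, 1/min.
#' @param tnf constant TNF level.
#' @param temp_base mean temperature, degrees C.
#' @param params,thermal model and thermal configuration.
#' @param d0 renormalised separation, uM.
#' @param tau renormalisation interval, min.
#' @param n_steps number of renormalisation intervals.
#' @param transient discarded transient, min.
#' @param init initial state.
#' @return The exponent, 1/min.
#' @export
lyapunov_exponent <- function(A_T, f_tmp, tnf = 0.5, temp_base = 37,
                              params = nfkb_params(),
                              thermal = thermal_config(),
                              d0 = 1e-7, tau = 10, n_steps = 400,
                              transient = 2000, init = default_init()) {
  forcing <- forcing_protocol(tnf_base = tnf, temp_base = temp_base,
                              temp_mode = if (A_T > 0) "sinusoid" else "constant",
                              temp_amplitude = A_T, temp_frequency = f_tmp)
  parms <- build_solver_parms(params, forcing, thermal)
  step <- function(y, t0) {
    sol <- deSolve::lsoda(unname(y), c(t0, t0 + tau), func = "nfkb_derivs",
                          parms = parms, dllname = "nfkbtherm",
                          initfunc = "nfkb_initmod", nout = 2,
                          rtol = 1e-8, atol = 1e-10, maxsteps = 500000)
    sol[nrow(sol), 2:6]
  }
  # settle onto the attractor
  pre <- simulate_nfkb(params, forcing, thermal, t_end = transient,
                       dt_out = transient / 4, transient_cut = 0, init = init)
  ya <- unlist(pre[nrow(pre), .state_names])
  yb <- ya + d0 / sqrt(5)
  logs <- numeric(n_steps)
  t0 <- transient
  for (i in seq_len(n_steps)) {
    ya <- step(ya, t0)
    yb <- step(yb, t0)
    t0 <- t0 + tau
    dv <- yb - ya
    d <- sqrt(sum(dv^2))
    logs[i] <- log(d / d0)
    yb <- ya + dv * (d0 / d)
  }
  sum(logs) / (n_steps * tau)
}
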
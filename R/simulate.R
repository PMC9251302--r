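#' Time derivatives of the NF-kB model state
#'
#' Reference (R-language) implementation of the model right-hand side. The
#' five equations describe nuclear NF-kB import/export gated by cytoplasmic
#' IkB, NF-kB-driven IkB transcription and translation, IKK-triggered IkB
#' degradation, and the TNF-driven IKK activation cycle with constitutive
#' A20 damping its recycling. All nine kinetic rates are first rescaled to
#' the instantaneous temperature `T(t)` via the thermal configuration
#' (quasi-static scaling: re-evaluated at every call).
#'
#' The same arithmetic is implemented in C for the production solver;
#' the two are cross-checked in the test suite.
#'
#' @param state named numeric vector `(N_n, I_m, I, IKK_a, IKK_i)` in uM.
#' @param t time in minutes.
#' @param params an [nfkb_params()] set defined at the thermal reference
#'   temperature.
#' @param forcing a [forcing_protocol()].
#' @param thermal a [thermal_config()].
#' @return Named numeric vector of the five derivatives (uM/min).
#' @examples
#' nfkb_rhs(default_init(), 0, nfkb_params(), forcing_protocol())
#' @export
nfkb_rhs <- function(state, t, params = nfkb_params(),
                     forcing = forcing_protocol(),
                     thermal = thermal_config()) {
  state <- validate_state(state, params)
  p <- apply_temperature(params, temperature_at(forcing, t), thermal)
  TNF <- tnf_at(forcing, t)
  N_n <- state[["N_n"]]; I_m <- state[["I_m"]]; I <- state[["I"]]
  IKK_a <- state[["IKK_a"]]; IKK_i <- state[["IKK_i"]]
  IKK_n <- p$IKK_tot - IKK_a - IKK_i
  c(
    N_n = p$k_Nin * (p$N_tot - N_n) * p$K_I / (p$K_I + I) -
      p$k_Iin * I * N_n / (p$K_N + N_n),
    I_m = p$k_t * N_n^2 - p$gamma_m * I_m,
    I = p$k_tl * I_m - p$alpha * IKK_a * (p$N_tot - N_n) * I / (p$K_I + I),
    IKK_a = p$k_a * TNF * IKK_n - p$k_i * IKK_a,
    IKK_i = p$k_i * IKK_a - p$k_p * IKK_i * p$k_A20 / (p$k_A20 + p$A20 * TNF)
  )
}

# flatten params + forcing + thermal into the fixed-layout vector the
# compiled derivative function expects
build_solver_parms <- function(params, forcing, thermal) {
  max_steps <- 32L
  step_t <- rep(0, max_steps)
  step_l <- rep(0, max_steps)
  n_steps <- 0
  if (forcing$tnf_mode == "steps") {
    n_steps <- nrow(forcing$tnf_steps)
    step_t[seq_len(n_steps)] <- forcing$tnf_steps$time
    step_l[seq_len(n_steps)] <- forcing$tnf_steps$level
  }
  c(
    unlist(params[.rate_names], use.names = FALSE),
    thermal_slopes(thermal),
    unlist(params[.const_names], use.names = FALSE),
    thermal$T_ref_K,
    match(forcing$temp_mode, c("constant", "sinusoid")) - 1,
    forcing$temp_base, forcing$temp_amplitude, forcing$temp_frequency,
    match(forcing$tnf_mode, c("constant", "sinusoid", "steps")) - 1,
    forcing$tnf_base, forcing$tnf_amplitude, forcing$tnf_period,
    n_steps, step_t, step_l
  )
}

#' Integrate the NF-kB model
#'
#' Adaptive, stiffness-switching integration (deSolve's `lsoda`) of the
#' five-variable model under the given forcing, with all rates rescaled to
#' the instantaneous temperature inside every derivative evaluation. Output
#' is sampled on a uniform grid. The neutral IKK fraction is derived as
#' `IKK_tot - IKK_a - IKK_i`, so the IKK pool is conserved exactly.
#'
#' The default tolerances (rtol 1e-8, atol 1e-10) are deliberately tight:
#' the IKK recycling term saturates sharply and the spiky limit cycles need
#' accurate integration for reliable spectra. Identical inputs give
#' bit-identical trajectories.
#'
#' @inheritParams nfkb_rhs
#' @param t_end end of the integration, minutes.
#' @param dt_out output grid spacing, minutes.
#' @param init initial state (named or positional, order
#'   `N_n, I_m, I, IKK_a, IKK_i`).
#' @param transient_cut length (min) of the initial window that analyses
#'   should discard; stored on the trajectory, not removed from it.
#' @param t_start start time, minutes (negative allowed, e.g. for protocols
#'   where the ligand is added shortly before imaging starts).
#' @param rtol,atol relative / absolute solver tolerances.
#' @param engine `"compiled"` (C right-hand side; default) or `"R"`
#'   (reference implementation, much slower).
#' @return A tibble of class `"nfkb_trajectory"` with columns `time`,
#'   `N_n`, `I_m`, `I`, `IKK_a`, `IKK_i`, `IKK_n`, `TNF`, `temperature_C`,
#'   and attributes `params`, `forcing`, `thermal`, `transient_cut`.
#' @examples
#' traj <- simulate_nfkb(t_end = 3000)
#' traj
#' @export
simulate_nfkb <- function(params = nfkb_params(),
                          forcing = forcing_protocol(),
                          thermal = thermal_config(),
                          t_end = 10000, dt_out = 1,
                          init = default_init(),
                          transient_cut = 2000,
                          t_start = 0,
                          rtol = 1e-8, atol = 1e-10,
                          engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  stopifnot(t_end > t_start, dt_out > 0, transient_cut >= 0)
  if (t_end - t_start <= transient_cut) {
    abort("t_end - t_start must exceed transient_cut")
  }
  init <- validate_state(init, params)
  times <- seq(t_start, t_end, by = dt_out)

  if (engine == "compiled") {
    parms <- build_solver_parms(params, forcing, thermal)
    sol <- deSolve::lsoda(
      y = unname(init), times = times, func = "nfkb_derivs",
      parms = parms, dllname = "nfkbtherm", initfunc = "nfkb_initmod",
      nout = 2, outnames = c("TNF", "temperature_C"),
      rtol = rtol, atol = atol, maxsteps = 500000
    )
  } else {
    rhs_fun <- function(t, y, p) {
      y <- setNames(y, .state_names)
      list(unname(nfkb_rhs(y, t, params, forcing, thermal)),
           TNF = tnf_at(forcing, t),
           temperature_C = temperature_at(forcing, t))
    }
    sol <- deSolve::lsoda(unname(init), times, rhs_fun, NULL,
                          rtol = rtol, atol = atol, maxsteps = 500000)
  }
  if (nrow(sol) < length(times)) {
    abort(sprintf("integration failed at t = %.3f min (step underflow or excessive work)",
                  max(sol[, 1])))
  }
  out <- as_tibble(as.data.frame(sol))
  names(out) <- c("time", .state_names, "TNF", "temperature_C")
  out$IKK_n <- params$IKK_tot - out$IKK_a - out$IKK_i
  out <- out[c("time", .state_names, "IKK_n", "TNF", "temperature_C")]
  new_trajectory(out, params, forcing, thermal, transient_cut)
}

new_trajectory <- function(df, params, forcing, thermal, transient_cut) {
  structure(df,
            class = c("nfkb_trajectory", class(tibble())),
            params = params, forcing = forcing, thermal = thermal,
            transient_cut = transient_cut)
}

#' Post-transient window of a trajectory
#'
#' @param traj an `nfkb_trajectory`.
#' @param transient_cut override of the stored transient cut (min).
#' @return The trajectory restricted to
#'   `time >= time[1] + transient_cut`.
#' @export
trajectory_window <- function(traj, transient_cut = NULL) {
  stopifnot(inherits(traj, "nfkb_trajectory"))
  cut <- transient_cut %||% attr(traj, "transient_cut")
  keep <- traj$time >= traj$time[1] + cut
  new_trajectory(traj[keep, ], attr(traj, "params"), attr(traj, "forcing"),
                 attr(traj, "thermal"), 0)
}

#' Evaluate the model right-hand side along a stored trajectory
#'
#' @param traj an `nfkb_trajectory`.
#' @return A tibble `time` plus the five derivatives (uM/min).
#' @export
trajectory_derivatives <- function(traj) {
  stopifnot(inherits(traj, "nfkb_trajectory"))
  params <- attr(traj, "params")
  thermal <- attr(traj, "thermal")
  # vectorised over the whole grid: rates rescaled per-row from the
  # stored temperature, same arithmetic as nfkb_rhs()
  slopes <- setNames(thermal_slopes(thermal), .rate_names)
  dT <- traj$temperature_C + 273.15 - thermal$T_ref_K
  r <- lapply(.rate_names, function(nm) {
    pmax(params[[nm]] * (1 + slopes[[nm]] * dT), 1e-12)
  })
  names(r) <- .rate_names
  N_n <- traj$N_n; I_m <- traj$I_m; I <- traj$I
  IKK_a <- traj$IKK_a; IKK_i <- traj$IKK_i
  TNF <- traj$TNF
  IKK_n <- params$IKK_tot - IKK_a - IKK_i
  tibble(
    time = traj$time,
    dN_n = r$k_Nin * (params$N_tot - N_n) * params$K_I / (params$K_I + I) -
      r$k_Iin * I * N_n / (params$K_N + N_n),
    dI_m = r$k_t * N_n^2 - r$gamma_m * I_m,
    dI = r$k_tl * I_m - r$alpha * IKK_a * (params$N_tot - N_n) * I /
      (params$K_I + I),
    dIKK_a = r$k_a * TNF * IKK_n - r$k_i * IKK_a,
    dIKK_i = r$k_i * IKK_a -
      r$k_p * IKK_i * params$k_A20 / (params$k_A20 + params$A20 * TNF)
  )
}

#' Write a trajectory to CSV
#'
#' Full double precision, header
#' `time_min,N_n,I_m,I,IKK_a,IKK_i,TNF,temperature_C`.
#'
#' @param traj an `nfkb_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "nfkb_trajectory"))
  out <- tibble(
    time_min = traj$time, N_n = traj$N_n, I_m = traj$I_m, I = traj$I,
    IKK_a = traj$IKK_a, IKK_i = traj$IKK_i, TNF = traj$TNF,
    temperature_C = traj$temperature_C
  )
  readr::write_csv(out, path)
  invisible(path)
}
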
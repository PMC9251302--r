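#' Downstream gene specification
#'
#' Hill-function transcription driven by nuclear NF-kB, linear translation
#' and first-order decay:
#' `dm/dt = gamma * N^h / (N^h + K^h) - delta * m`,
#' `dP/dt = Gamma * m - Delta * P`.
#' `K` is the effective affinity: the nuclear NF-kB concentration giving
#' half-maximal transcription. `h` is the Hill coefficient
#' (cooperativity).
#'
#' The default decay times (mRNA ~33 min half-life via `delta`, protein
#' ~69 min via `Delta`) are slow against the ~100-min oscillation period,
#' so the protein level time-averages the transcriptional drive.
#'
#' @param name gene label.
#' @param gamma maximal transcription rate, uM/min.
#' @param delta mRNA decay rate, 1/min.
#' @param Gamma translation rate, 1/min.
#' @param Delta protein decay rate, 1/min.
#' @param h Hill coefficient (>= 1).
#' @param K effective affinity, uM.
#' @return An object of class `"gene_spec"`.
#' @export
gene_spec <- function(name, gamma = 1, delta = 0.03, Gamma = 1,
                      Delta = 0.01, h, K) {
  vals <- c(gamma = gamma, delta = delta, Gamma = Gamma, Delta = Delta,
            h = h, K = K)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    abort("all gene parameters must be finite and positive")
  }
  if (h < 1) abort("Hill coefficient h must be >= 1")
  structure(list(name = name, gamma = gamma, delta = delta, Gamma = Gamma,
                 Delta = Delta, h = h, K = K), class = "gene_spec")
}

#' @describeIn gene_spec a high-affinity, low-cooperativity gene
#'   (K = 0.05 uM, h = 2): near-saturated through most of the NF-kB cycle,
#'   starved only in deep troughs.
#' @export
high_affinity_gene <- function() gene_spec("Protein1", h = 2, K = 0.05)

#' @describeIn gene_spec a low-affinity, high-cooperativity gene
#'   (K = 0.8 uM, h = 4): expressed only near the highest NF-kB peaks.
#' @export
low_affinity_gene <- function() gene_spec("Protein2", h = 4, K = 0.8)

#' Time derivatives of a downstream gene state
#'
#' @param state numeric `(m, P)` in uM.
#' @param N_n nuclear NF-kB concentration, uM (>= 0).
#' @param spec a [gene_spec()].
#' @return Named vector `(m, P)` of derivatives, uM/min.
#' @export
gene_rhs <- function(state, N_n, spec) {
  stopifnot(N_n >= 0)
  hill <- N_n^spec$h / (N_n^spec$h + spec$K^spec$h)
  c(m = spec$gamma * hill - spec$delta * state[[1]],
    P = spec$Gamma * state[[1]] - spec$Delta * state[[2]])
}

#' Integrate downstream genes driven by a stored NF-kB trajectory
#'
#' Co-integrates the mRNA/protein equations of each gene against the
#' nuclear NF-kB series of `traj` (linearly interpolated between output
#' points).
#'
#' @param traj an `nfkb_trajectory`.
#' @param specs a `gene_spec` or list of them.
#' @param init initial `(m, P)` state, uM.
#' @return A tibble `time`, `gene`, `m`, `P`.
#' @export
simulate_genes <- function(traj, specs, init = c(m = 0, P = 0)) {
  stopifnot(inherits(traj, "nfkb_trajectory"))
  if (inherits(specs, "gene_spec")) specs <- list(specs)
  drive <- approxfun(traj$time, traj$N_n, rule = 2)
  purrr::map_dfr(specs, function(spec) {
    sol <- deSolve::lsoda(
      y = unname(init), times = traj$time,
      func = function(t, y, p) list(unname(gene_rhs(y, drive(t), spec))),
      parms = NULL, rtol = 1e-8, atol = 1e-10
    )
    tibble(time = sol[, 1], gene = spec$name, m = sol[, 2], P = sol[, 3])
  })
}

#' Steady-state protein level under an oscillating NF-kB drive
#'
#' Integrates the gene against the stored trajectory and averages the
#' protein over the final 20% of the post-transient window. The window
#' must cover at least ten protein half-lives `ln(2)/Delta` so the
#' average is taken at quasi-steady state.
#'
#' @param traj an `nfkb_trajectory`.
#' @param spec a [gene_spec()].
#' @return Time-averaged protein level, uM.
#' @export
steady_state_protein <- function(traj, spec) {
  cut <- attr(traj, "transient_cut")
  horizon <- diff(range(traj$time)) - cut
  need <- 10 * log(2) / spec$Delta
  if (horizon < need) {
    abort(sprintf("post-transient window (%.0f min) must cover 10 protein half-lives (%.0f min)",
                  horizon, need))
  }
  g <- simulate_genes(traj, spec)
  t_hi <- max(g$time)
  t_lo <- t_hi - 0.2 * horizon
  mean(g$P[g$time >= t_lo])
}

#' Steady-state protein levels across a temperature grid
#'
#' @param specs a `gene_spec` or list of them.
#' @param temperatures working temperatures, degrees C.
#' @param tnf constant TNF level.
#' @param params,thermal model and thermal configuration.
#' @param t_end,transient_cut simulation controls (one NF-kB simulation
#'   per temperature, shared by all genes).
#' @return A tibble `temperature_C`, `gene`, `steady_P`.
#' @export
protein_temperature_profile <- function(specs,
                                        temperatures = seq(32, 41.5, by = 0.5),
                                        tnf = 0.5,
                                        params = nfkb_params(),
                                        thermal = thermal_config(),
                                        t_end = 10000, transient_cut = 2000) {
  if (inherits(specs, "gene_spec")) specs <- list(specs)
  purrr::map_dfr(temperatures, function(Tc) {
    traj <- simulate_nfkb(params,
                          forcing_protocol(tnf_base = tnf, temp_base = Tc),
                          thermal, t_end = t_end,
                          transient_cut = transient_cut)
    tibble(
      temperature_C = Tc,
      gene = purrr::map_chr(specs, "name"),
      steady_P = purrr::map_dbl(specs, ~ steady_state_protein(traj, .x))
    )
  })
}

#' Temperature crossover of relative protein production
#'
#' Normalises each gene's steady-state protein curve by its own value at
#' the reference temperature and locates the temperature where the two
#' normalised curves intersect (linear interpolation between bracketing
#' grid points). The intersection is symmetric: swapping the two genes
#' leaves it unchanged. With no sign change on the grid (e.g. identical
#' specs) a no-crossover result is returned, not an error.
#'
#' @param spec_high,spec_low the two [gene_spec()]s to compare.
#' @param temperatures temperature grid (must contain `ref_temp`).
#' @param tnf constant TNF level.
#' @param ref_temp normalisation temperature, degrees C.
#' @inheritParams protein_temperature_profile
#' @return A one-row tibble `crossover_C`, `found`, `n_crossings`, with
#'   the relative-production profiles in attribute `"profiles"`.
#' @export
crossover_temperature <- function(spec_high, spec_low,
                                  temperatures = seq(32, 41.5, by = 0.5),
                                  tnf = 0.5, ref_temp = 37,
                                  params = nfkb_params(),
                                  thermal = thermal_config(),
                                  t_end = 10000, transient_cut = 2000) {
  if (!any(abs(temperatures - ref_temp) < 1e-9)) {
    abort("ref_temp must be one of the grid temperatures")
  }
  prof <- protein_temperature_profile(list(spec_high, spec_low), temperatures,
                                      tnf, params, thermal, t_end,
                                      transient_cut)
  prof <- prof |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(relative = .data$steady_P /
                    .data$steady_P[abs(.data$temperature_C - ref_temp) < 1e-9]) |>
    dplyr::ungroup()
  wide <- tidyr::pivot_wider(prof[c("temperature_C", "gene", "relative")],
                             names_from = "gene", values_from = "relative")
  d <- wide[[spec_high$name]] - wide[[spec_low$name]]
  # treat numerically identical curves as crossover-free
  if (all(abs(d) < 1e-9)) {
    res <- tibble(crossover_C = NA_real_, found = FALSE, n_crossings = 0L)
  } else {
    s <- sign(d)
    cross <- which(s[-1] * s[-length(s)] < 0 |
                     (s[-length(s)] != 0 & s[-1] == 0))
    if (!length(cross)) {
      res <- tibble(crossover_C = NA_real_, found = FALSE, n_crossings = 0L)
    } else {
      i <- cross[1]
      x <- wide$temperature_C
      tc <- x[i] + (x[i + 1] - x[i]) * d[i] / (d[i] - d[i + 1])
      res <- tibble(crossover_C = tc, found = TRUE,
                    n_crossings = length(cross))
    }
  }
  attr(res, "profiles") <- prof
  res
}
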
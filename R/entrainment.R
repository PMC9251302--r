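#' Rotation number under sinusoidal temperature forcing
#'
#' Forces the model with `T(t) = temp_base + A_T sin(2 pi f_tmp t)` at
#' constant TNF and measures the rotation number
#' `W = f_tmp / f_NFkB`: forcing cycles divided by the number of nuclear
#' NF-kB response peaks counted over exactly `n_cycles` forcing periods
#' (after discarding `transient_cycles`). Peaks are local maxima with
#' prominence at least 5% of the post-transient amplitude.
#'
#' Because the raw count is quantized by boundary peaks, a refined
#' estimate `W_refined` from the mean inter-peak interval is attached and
#' used to assign a locked rational `p/q` (q <= 8) within tolerance
#' `lock_tol`.
#'
#' @param A_T temperature oscillation amplitude, degrees C (>= 0).
#' @param f_tmp forcing frequency, 1/min (> 0).
#' @param tnf constant TNF level.
#' @param temp_base mean temperature, degrees C.
#' @param params,thermal model and thermal configuration.
#' @param n_cycles forcing cycles counted (default 200).
#' @param transient_cycles forcing cycles discarded first (default 50).
#' @param dt_out output grid, min.
#' @param lock_tol tolerance on |W - p/q| for declaring a lock.
#' @param init initial state.
#' @return A one-row tibble of class `"nfkb_entrainment"`: `f_tmp`, `A_T`,
#'   `tnf`, `W`, `W_refined`, `locked_p`, `locked_q`, `locked_ratio`,
#'   `n_forcing_cycles`, `n_response_peaks`, `degenerate`.
#' @export
rotation_number <- function(A_T, f_tmp, tnf = 0.5, temp_base = 37,
                            params = nfkb_params(),
                            thermal = thermal_config(),
                            n_cycles = 200, transient_cycles = 50,
                            dt_out = 0.5, lock_tol = 5e-3,
                            init = default_init()) {
  stopifnot(A_T >= 0, f_tmp > 0)
  Tf <- 1 / f_tmp
  t_trans <- transient_cycles * Tf
  t_end <- t_trans + n_cycles * Tf
  forcing <- forcing_protocol(tnf_base = tnf, temp_base = temp_base,
                              temp_mode = if (A_T > 0) "sinusoid" else "constant",
                              temp_amplitude = A_T, temp_frequency = f_tmp)
  traj <- simulate_nfkb(params, forcing, thermal, t_end = t_end,
                        dt_out = dt_out, transient_cut = t_trans,
                        init = init)
  w <- trajectory_window(traj)
  # exactly n_cycles forcing periods: [t_trans, t_trans + n_cycles*Tf)
  w <- w[w$time < t_trans + n_cycles * Tf, ]
  amp <- diff(range(w$N_n))
  pk <- if (amp > 1e-6) find_peaks(w$N_n, min_prominence = 0.05 * amp) else
    tibble(idx = integer())
  n_peaks <- nrow(pk)
  if (n_peaks == 0L) {
    out <- tibble(f_tmp = f_tmp, A_T = A_T, tnf = tnf,
                  W = NA_real_, W_refined = NA_real_,
                  locked_p = NA_integer_, locked_q = NA_integer_,
                  locked_ratio = NA_character_,
                  n_forcing_cycles = n_cycles, n_response_peaks = 0L,
                  degenerate = TRUE)
    return(structure(out, class = c("nfkb_entrainment", class(tibble()))))
  }
  W <- n_cycles / n_peaks
  W_ref <- if (n_peaks >= 3L) mean(diff(w$time[pk$idx])) / Tf else W
  lock <- detect_lock(W_ref, lock_tol)
  out <- tibble(
    f_tmp = f_tmp, A_T = A_T, tnf = tnf, W = W, W_refined = W_ref,
    locked_p = lock$p, locked_q = lock$q, locked_ratio = lock$label,
    n_forcing_cycles = n_cycles, n_response_peaks = n_peaks,
    degenerate = FALSE
  )
  structure(out, class = c("nfkb_entrainment", class(tibble())))
}

# nearest rational p/q with q <= 8 within tol of W (smallest q wins)
detect_lock <- function(W, tol = 5e-3) {
  if (!is.finite(W)) {
    return(list(p = NA_integer_, q = NA_integer_, label = NA_character_))
  }
  for (q in 1:8) {
    p <- round(W * q)
    if (p >= 1 && abs(W - p / q) < tol) {
      g <- gcd_int(p, q)
      return(list(p = as.integer(p / g), q = as.integer(q / g),
                  label = sprintf("%d/%d", p / g, q / g)))
    }
  }
  list(p = NA_integer_, q = NA_integer_, label = NA_character_)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Devil's staircase: rotation number across a forcing-frequency grid
#'
#' One [rotation_number()] per grid frequency. Plateaus (maximal runs of
#' identical locked ratio) are labelled in `plateau_id`.
#'
#' @param f_grid increasing forcing frequencies, 1/min.
#' @inheritParams rotation_number
#' @param ... passed to [rotation_number()].
#' @return A tibble of class `"nfkb_staircase"` with one row per
#'   frequency and a `plateau_id` column (NA off-plateau).
#' @export
devils_staircase <- function(f_grid, A_T, tnf = 0.5, ...) {
  if (is.unsorted(f_grid, strictly = TRUE)) {
    abort("f_grid must be strictly increasing")
  }
  rows <- purrr::map_dfr(f_grid, function(f) {
    rotation_number(A_T = A_T, f_tmp = f, tnf = tnf, ...)
  })
  runs <- rle(ifelse(is.na(rows$locked_ratio), "<none>", rows$locked_ratio))
  ids <- rep(seq_along(runs$lengths), runs$lengths)
  ids[is.na(rows$locked_ratio)] <- NA_integer_
  rows$plateau_id <- ids
  structure(rows, class = c("nfkb_staircase", class(tibble())))
}

#' Width of a p/q entrainment plateau
#'
#' Starting from a frequency known to lie inside the plateau, each edge is
#' located by bisection between the last locked and first unlocked
#' frequency, to resolution `tol`.
#'
#' @param p,q the locked rational (coprime).
#' @param A_T forcing amplitude, degrees C.
#' @param tnf constant TNF level.
#' @param f_seed a forcing frequency inside the plateau.
#' @param tol edge resolution, 1/min.
#' @param step initial outward search step, 1/min.
#' @param ... passed to [rotation_number()] (e.g. reduced `n_cycles`).
#' @return A one-row tibble `p`, `q`, `A_T`, `tnf`, `f_low`, `f_high`,
#'   `width`.
#' @export
plateau_width <- function(p, q, A_T, tnf = 0.5, f_seed, tol = 1e-5,
                          step = 2e-3, ...) {
  locked_here <- function(f) {
    r <- rotation_number(A_T = A_T, f_tmp = f, tnf = tnf, ...)
    !is.na(r$locked_p) && r$locked_p == p && r$locked_q == q
  }
  if (!locked_here(f_seed)) {
    abort(sprintf("f_seed = %.4g is not locked to %d/%d", f_seed, p, q))
  }
  edge <- function(dir) {
    f_in <- f_seed
    f_out <- f_seed + dir * step
    k <- 0
    while (f_out > 0 && locked_here(f_out)) {
      f_in <- f_out
      f_out <- f_out + dir * step * 2^k
      k <- k + 1
      if (k > 12) abort("plateau edge not found within search range")
    }
    if (f_out <= 0) f_out <- tol / 2
    while (abs(f_out - f_in) > tol) {
      mid <- (f_in + f_out) / 2
      if (locked_here(mid)) f_in <- mid else f_out <- mid
    }
    (f_in + f_out) / 2
  }
  f_hi <- edge(+1)
  f_lo <- edge(-1)
  tibble(p = p, q = q, A_T = A_T, tnf = tnf,
         f_low = f_lo, f_high = f_hi, width = f_hi - f_lo)
}

#' Count coexisting limit cycles under temperature forcing
#'
#' Integrates the forced model from `n_ics` random admissible initial
#' conditions and clusters the post-transient orbits: orbits that trace
#' the same closed curve in `(N_n, I_m, I)` space, possibly shifted in
#' phase, count as one attractor.
#'
#' With periodic forcing an entrained orbit repeats after `q` forcing
#' periods (q <= 8 searched) and two solutions on the same attractor
#' differ exactly by an integer number of forcing periods, so orbits are
#' sampled on a grid commensurate with the forcing period and compared
#' pointwise under every cyclic shift by whole forcing periods; the
#' attractor distance is the minimum over shifts of the maximal
#' phase-space distance, which is free of interpolation error. Orbits
#' that do not repeat within `q_max` forcing periods (quasiperiodic,
#' chaotic or unconverged) are flagged and excluded from the limit-cycle
#' count. In the unforced case (`A_T = 0`) the phase shift is continuous;
#' orbits are then aligned at their (parabolically refined) nuclear-NF-kB
#' peak times on a fine grid before the pointwise comparison.
#'
#' @param A_T forcing amplitude, degrees C.
#' @param f_tmp forcing frequency, 1/min.
#' @param tnf constant TNF level.
#' @param n_ics number of random initial conditions (>= 2).
#' @param seed seed for the initial-condition draws.
#' @param temp_base mean temperature, degrees C.
#' @param params,thermal model and thermal configuration.
#' @param transient discarded transient, min.
#' @param q_max largest period (in forcing cycles) searched.
#' @param threshold clustering distance threshold, uM.
#' @return A list of class `"nfkb_multistability"`: `n_attractors`,
#'   `n_flagged` (non-periodic orbits), `assignments` (tibble: ic,
#'   attractor id or NA, periodic, q), `representatives` (list of orbit
#'   matrices), and the call parameters.
#' @export
multistability_scan <- function(A_T, f_tmp, tnf = 0.5, n_ics = 40, seed = 1,
                                temp_base = 37,
                                params = nfkb_params(),
                                thermal = thermal_config(),
                                transient = 20000, q_max = 8,
                                threshold = 1e-3) {
  stopifnot(n_ics >= 2)
  forced <- A_T > 0
  forcing <- forcing_protocol(tnf_base = tnf, temp_base = temp_base,
                              temp_mode = if (forced) "sinusoid" else "constant",
                              temp_amplitude = A_T, temp_frequency = f_tmp)
  Tf <- 1 / f_tmp
  if (forced) {
    m <- 128L                              # samples per forcing period
    dt <- Tf / m
    n_orbit <- 2L * q_max * m              # 2*q_max forcing periods
  } else {
    dt <- 0.02
    n_orbit <- round(6 * 150 / dt)         # ~6 natural periods
  }
  orbits <- purrr::map(seq_len(n_ics), function(i) {
    ic <- random_initial_state(child_seed(seed, i), params)
    # coarse pass through the transient, fine sampling of the orbit only
    pre <- simulate_nfkb(params, forcing, thermal, t_end = transient,
                         dt_out = transient / 4, transient_cut = 0,
                         init = ic)
    y0 <- unlist(pre[nrow(pre), .state_names])
    traj <- simulate_nfkb(params, forcing, thermal, t_start = transient,
                          t_end = transient + (n_orbit + 1) * dt, dt_out = dt,
                          transient_cut = 0, init = y0)
    as.matrix(traj[seq_len(n_orbit), c("N_n", "I_m", "I")])
  })

  if (forced) {
    # smallest q with the orbit repeating after q forcing periods
    find_q <- function(orb) {
      for (q in seq_len(q_max)) {
        lag <- q * m
        idx <- seq_len(n_orbit - lag)
        if (max(abs(orb[idx, ] - orb[idx + lag, ])) < threshold) return(q)
      }
      NA_integer_
    }
    qs <- purrr::map_int(orbits, find_q)
    orbit_dist <- function(a, b, q) {
      idx <- seq_len(q_max * m)            # compare over q_max periods
      min(purrr::map_dbl(seq_len(q) - 1L, function(k) {
        max(abs(a[idx, ] - b[idx + k * m, ]))
      }))
    }
  } else {
    # unforced oscillator: single-period repetition at the natural period
    qs <- rep(1L, n_ics)
    orbit_dist <- function(a, b, q) aligned_orbit_distance(a, b, dt)
  }

  reps <- list()
  rep_q <- integer()
  assign <- rep(NA_integer_, n_ics)
  for (i in seq_len(n_ics)) {
    if (is.na(qs[i])) next
    hit <- 0L
    for (j in seq_along(reps)) {
      if (rep_q[j] == qs[i] &&
          orbit_dist(orbits[[i]], reps[[j]], qs[i]) < threshold) {
        hit <- j
        break
      }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- orbits[[i]]
      rep_q <- c(rep_q, qs[i])
      hit <- length(reps)
    }
    assign[i] <- hit
  }
  structure(list(
    n_attractors = length(reps),
    n_flagged = sum(is.na(qs)),
    assignments = tibble(ic = seq_len(n_ics), attractor = assign,
                         periodic = !is.na(qs), q = qs),
    representatives = reps,
    A_T = A_T, f_tmp = f_tmp, tnf = tnf, seed = seed, threshold = threshold
  ), class = "nfkb_multistability")
}

# maximal pointwise distance between two unforced orbits after aligning
# their first refined N_n peak times (linear interpolation on the fine
# grid; both orbits must cover several periods)
aligned_orbit_distance <- function(a, b, dt) {
  peak_time <- function(orb) {
    pk <- find_peaks(orb[, 1], min_prominence = 0.05 * diff(range(orb[, 1])))
    if (!nrow(pk)) return(NA_real_)
    i <- pk$idx[1]
    if (i <= 1L || i >= nrow(orb)) return((i - 1) * dt)
    (i - 1 + parabolic_offset(orb[i - 1, 1], orb[i, 1], orb[i + 1, 1])) * dt
  }
  ta <- peak_time(a); tb <- peak_time(b)
  if (is.na(ta) || is.na(tb)) {
    # no peaks: both at fixed points; compare final states
    return(max(abs(a[nrow(a), ] - b[nrow(b), ])))
  }
  shift <- tb - ta
  if (shift < 0) {
    # use the next peak of b so the evaluation stays inside its window
    pk_b <- find_peaks(b[, 1], min_prominence = 0.05 * diff(range(b[, 1])))
    period_b <- if (nrow(pk_b) >= 2L) mean(diff(pk_b$idx)) * dt else -shift
    shift <- shift + period_b * ceiling(-shift / period_b)
  }
  n <- nrow(a)
  t_grid <- (seq_len(n) - 1) * dt
  n_cmp <- floor(0.6 * n)
  t_cmp <- t_grid[seq_len(n_cmp)]
  d <- purrr::map_dbl(1:3, function(col) {
    fb <- approxfun(t_grid, b[, col], rule = 2)
    max(abs(a[seq_len(n_cmp), col] - fb(t_cmp + shift)))
  })
  max(d)
}

#' @export
print.nfkb_multistability <- function(x, ...) {
  cat(sprintf("<nfkb_multistability> A_T = %.2f degC, f_tmp = %.4g /min: %d attractor(s) over %d initial conditions\n",
              x$A_T, x$f_tmp, x$n_attractors, nrow(x$assignments)))
  invisible(x)
}
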
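# shared fixtures: short simulations reused across tests

sim_37 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- simulate_nfkb(t_end = 8000)
    val
  }
})

sim_at <- function(temp, tnf = 0.5, t_end = 8000, transient_cut = 2000, ...) {
  simulate_nfkb(forcing = forcing_protocol(tnf_base = tnf, temp_base = temp),
                t_end = t_end, transient_cut = transient_cut, ...)
}

# independent fixed-step classical Runge-Kutta oracle for the adaptive
# solver: the model equations are written out by hand here (constant TNF
# and temperature), deliberately not calling the package's rhs
rk4_integrate <- function(init, t_end, dt, p, tnf, sample_every = 1000L) {
  deriv <- function(y) {
    N_n <- y[1]; I_m <- y[2]; I <- y[3]; IKK_a <- y[4]; IKK_i <- y[5]
    IKK_n <- p$IKK_tot - IKK_a - IKK_i
    c(p$k_Nin * (p$N_tot - N_n) * p$K_I / (p$K_I + I) -
        p$k_Iin * I * N_n / (p$K_N + N_n),
      p$k_t * N_n^2 - p$gamma_m * I_m,
      p$k_tl * I_m - p$alpha * IKK_a * (p$N_tot - N_n) * I / (p$K_I + I),
      p$k_a * tnf * IKK_n - p$k_i * IKK_a,
      p$k_i * IKK_a - p$k_p * IKK_i * p$k_A20 / (p$k_A20 + p$A20 * tnf))
  }
  y <- unname(init)
  n <- round(t_end / dt)
  out_t <- numeric(0)
  out_y <- list()
  for (i in seq_len(n)) {
    k1 <- deriv(y)
    k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2)
    k4 <- deriv(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i %% sample_every == 0L) {
      out_t <- c(out_t, i * dt)
      out_y[[length(out_y) + 1L]] <- y
    }
  }
  list(time = out_t, state = do.call(rbind, out_y))
}
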
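#' Kinetic parameters of the NF-kB negative-feedback model
#'
#' Builds the set of fifteen model constants. The defaults are the published
#' reference values at 37 degrees C for the five-variable NF-kB / IkB / IKK
#' model: nine kinetic rates plus six temperature-independent constants
#' (binding constants, total pool sizes and the constitutive A20 level).
#'
#' Units: `k_Nin`, `k_Iin`, `k_tl`, `gamma_m`, `k_a`, `k_i`, `k_p` are in
#' 1/min; `k_t` and `alpha` in 1/(uM min); `K_I`, `K_N`, `N_tot`, `k_A20`,
#' `IKK_tot` and `A20` in uM.
#'
#' @param ... named overrides of individual parameters, e.g. `k_i = 0.2`.
#'   Unknown names are an error; all values must be finite and strictly
#'   positive.
#'
#' @return A named list of class `"nfkb_params"`.
#' @examples
#' nfkb_params()
#' nfkb_params(IKK_tot = 2.5)
#' @export
nfkb_params <- function(...) {
  defaults <- list(
    k_Nin   = 5.4,    # nuclear import of free NF-kB
    k_Iin   = 0.018,  # NF-kB:IkB complex formation / nuclear export
    k_t     = 1.03,   # NF-kB-driven IkB transcription
    k_tl    = 0.24,   # IkB translation
    K_I     = 0.035,  # IkB saturation of nuclear import inhibition
    K_N     = 0.029,  # NF-kB saturation of the export term
    gamma_m = 0.017,  # IkB mRNA decay
    alpha   = 1.05,   # IKKa-triggered IkB degradation
    N_tot   = 1.0,    # total NF-kB pool
    k_a     = 0.24,   # TNF-driven IKK activation
    k_i     = 0.18,   # IKK inactivation
    k_p     = 0.036,  # IKK recycling (inactive -> neutral)
    k_A20   = 0.0018, # A20 saturation of IKK recycling
    IKK_tot = 2.0,    # total IKK pool
    A20     = 0.0026  # constitutive A20 level
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    }
    defaults <- modifyList(defaults, overrides)
  }
  validate_nfkb_params(structure(defaults, class = "nfkb_params"))
}

validate_nfkb_params <- function(p) {
  vals <- unlist(p)
  if (length(vals) != 15L || !all(is.finite(vals)) || any(vals <= 0)) {
    abort("all 15 model parameters must be finite and strictly positive")
  }
  p
}

#' @export
print.nfkb_params <- function(x, ...) {
  cat("<nfkb_params>\n")
  print(tibble(parameter = names(x), value = unlist(x)), n = 15)
  invisible(x)
}

# canonical orderings shared with the compiled right-hand side
.rate_names <- c("k_Nin", "k_Iin", "k_t", "k_tl", "gamma_m",
                 "alpha", "k_a", "k_i", "k_p")
.const_names <- c("K_I", "K_N", "N_tot", "k_A20", "IKK_tot", "A20")
.state_names <- c("N_n", "I_m", "I", "IKK_a", "IKK_i")

#' Default initial model state
#'
#' An admissible starting point `(N_n, I_m, I, IKK_a, IKK_i)` in uM. Any
#' point satisfying the state bounds works because all analyses discard a
#' transient before measuring the attractor.
#'
#' @return A named numeric vector of length 5.
#' @export
default_init <- function() {
  c(N_n = 0.1, I_m = 0.01, I = 0.5, IKK_a = 0.1, IKK_i = 0.1)
}

validate_state <- function(state, params, tol = 1e-9) {
  if (!is.numeric(state) || length(state) != 5L) {
    abort("state must be a numeric vector of length 5 (N_n, I_m, I, IKK_a, IKK_i)")
  }
  if (!all(is.finite(state))) abort("non-finite state component")
  state <- setNames(as.numeric(state), .state_names)
  if (any(state < -tol)) abort("state components must be non-negative")
  if (state[["N_n"]] > params$N_tot + tol) abort("N_n exceeds N_tot")
  if (state[["IKK_a"]] + state[["IKK_i"]] > params$IKK_tot + tol) {
    abort("IKK_a + IKK_i exceeds IKK_tot")
  }
  state
}
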
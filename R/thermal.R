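#' Linear temperature scaling of a reaction-limited (Arrhenius) rate
#'
#' Rescales a reference rate `k0`, defined at absolute temperature `T_ref`,
#' to a temperature offset `dT` kelvin away, using the linearised Arrhenius
#' difference law `k = k0 * (1 + S * dT / T_ref)`. `S` is the dimensionless
#' activation scale factor (the log-ratio of the Arrhenius prefactor to the
#' reference rate); larger `S` means stronger temperature sensitivity.
#'
#' For physiological offsets (|dT| <= 10 K) with S <= 20 the factor stays
#' positive; should it not, the result is clamped at 1e-12 with a warning.
#'
#' @param k0 reference rate (> 0), any rate unit.
#' @param S dimensionless scale factor (> 0).
#' @param dT temperature offset in kelvin (equivalently degrees C).
#' @param T_ref reference absolute temperature in kelvin.
#' @return The rescaled rate, same unit as `k0`.
#' @seealso [scale_diffusion_limited()], [apply_temperature()]
#' @examples
#' scale_reaction_limited(0.18, S = 20, dT = -5)
#' @export
scale_reaction_limited <- function(k0, S, dT, T_ref = 310.15) {
  stopifnot(all(k0 > 0), all(S > 0), all(T_ref > 0))
  out <- k0 * (1 + S * dT / T_ref)
  if (any(out <= 0)) {
    warn("reaction-limited scaling produced a non-positive rate; clamped to 1e-12")
    out <- pmax(out, 1e-12)
  }
  out
}

#' Linear temperature scaling of a diffusion-limited (Smoluchowski) rate
#'
#' Rescales a diffusion-limited rate using the Einstein-Stokes slope,
#' `k = k0 * (1 + dT / T_ref)`: the encounter rate follows the diffusion
#' coefficient, which is linear in absolute temperature.
#'
#' @inheritParams scale_reaction_limited
#' @return The rescaled rate.
#' @examples
#' scale_diffusion_limited(5.4, dT = 4.5)
#' @export
scale_diffusion_limited <- function(k0, dT, T_ref = 310.15) {
  stopifnot(all(k0 > 0), all(T_ref > 0))
  k0 * (1 + dT / T_ref)
}

#' Default thermal-law assignment for the nine kinetic rates
#'
#' The three fastest rates (`k_Nin`, `k_t`, `alpha`) are treated as
#' diffusion limited; the remaining six follow the reaction-limited law,
#' with scale factor `S = 20` for the three most impactful (`k_Iin`, `k_i`,
#' `k_p`) and `S = 1` for the rest. The six non-rate constants are
#' temperature independent.
#'
#' @return A tibble with columns `rate`, `law`
#'   (`"diffusion"`, `"reaction"` or `"none"`) and `S`.
#' @export
default_thermal_laws <- function() {
  tibble(
    rate = c(.rate_names, .const_names),
    law  = c("diffusion", "reaction", "diffusion", "reaction", "reaction",
             "diffusion", "reaction", "reaction", "reaction",
             rep("none", 6)),
    S    = c(NA, 20, NA, 1, 1, NA, 1, 20, 20, rep(NA, 6))
  )
}

#' Thermal configuration: reference temperature and per-rate scaling laws
#'
#' @param T_ref_K absolute reference temperature (kelvin) at which the model
#'   parameters are defined. Defaults to 310.15 K (37 degrees C), the
#'   physiological baseline.
#' @param laws a tibble/data frame with columns `rate`, `law`, `S` covering
#'   all 15 parameters, as produced by [default_thermal_laws()].
#' @return An object of class `"thermal_config"`.
#' @examples
#' thermal_config()
#' # make every rate reaction-limited with S = 1 (pure Arrhenius variant)
#' laws <- default_thermal_laws()
#' laws$law[laws$law == "diffusion"] <- "reaction"
#' laws$S[laws$law == "reaction" & is.na(laws$S)] <- 1
#' thermal_config(laws = laws)
#' @export
thermal_config <- function(T_ref_K = 310.15, laws = default_thermal_laws()) {
  stopifnot(is.numeric(T_ref_K), length(T_ref_K) == 1L, T_ref_K > 0)
  laws <- as_tibble(laws)
  need <- c(.rate_names, .const_names)
  if (!all(c("rate", "law", "S") %in% names(laws))) {
    abort("laws must have columns rate, law, S")
  }
  if (!setequal(laws$rate, need) || anyDuplicated(laws$rate)) {
    abort("laws must cover exactly the 9 rates and 6 constants, once each")
  }
  if (!all(laws$law %in% c("diffusion", "reaction", "none"))) {
    abort("law must be one of 'diffusion', 'reaction', 'none'")
  }
  bad_s <- laws$law == "reaction" & (is.na(laws$S) | laws$S <= 0)
  if (any(bad_s)) {
    abort(paste0("reaction-limited rates need S > 0: ",
                 paste(laws$rate[bad_s], collapse = ", ")))
  }
  structure(list(T_ref_K = T_ref_K, laws = laws), class = "thermal_config")
}

#' @export
print.thermal_config <- function(x, ...) {
  cat(sprintf("<thermal_config> T_ref = %.2f K (%.2f degC)\n",
              x$T_ref_K, x$T_ref_K - 273.15))
  print(x$laws, n = 15)
  invisible(x)
}

# per-kelvin slope coefficient of each of the nine rates, in rhs order
thermal_slopes <- function(thermal) {
  laws <- thermal$laws[match(.rate_names, thermal$laws$rate), ]
  dplyr::case_when(
    laws$law == "diffusion" ~ 1 / thermal$T_ref_K,
    laws$law == "reaction"  ~ laws$S / thermal$T_ref_K,
    .default = 0
  )
}

#' Rescale a parameter set to a given temperature
#'
#' Maps the reference parameter set (defined at `thermal$T_ref_K`) to the
#' working temperature: each of the nine kinetic rates is rescaled by its
#' assigned law and the six non-rate constants are returned untouched.
#'
#' @param params an [nfkb_params()] set defined at the reference temperature.
#' @param T_celsius working temperature in degrees C.
#' @param thermal a [thermal_config()].
#' @return A new `nfkb_params` object valid at `T_celsius`.
#' @examples
#' apply_temperature(nfkb_params(), 32)
#' @export
apply_temperature <- function(params, T_celsius, thermal = thermal_config()) {
  stopifnot(inherits(params, "nfkb_params"), is.numeric(T_celsius),
            length(T_celsius) == 1L)
  dT <- T_celsius + 273.15 - thermal$T_ref_K
  laws <- thermal$laws
  out <- params
  for (r in .rate_names) {
    law <- laws$law[laws$rate == r]
    if (length(law) != 1L) abort(paste0("rate missing from law map: ", r))
    out[[r]] <- switch(law,
      diffusion = scale_diffusion_limited(params[[r]], dT, thermal$T_ref_K),
      reaction  = scale_reaction_limited(params[[r]], laws$S[laws$rate == r],
                                         dT, thermal$T_ref_K),
      none      = params[[r]]
    )
  }
  validate_nfkb_params(out)
}
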
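test_that("reaction-limited scaling matches hand-evaluated values", {
  # dT = 0 identity
  expect_identical(scale_reaction_limited(0.18, S = 20, dT = 0), 0.18)
  # hand evaluation: k0 * (1 + S * dT / T_ref)
  expect_equal(scale_reaction_limited(0.18, S = 20, dT = -5, T_ref = 310.15),
               0.18 * (1 - 100 / 310.15), tolerance = 1e-12)
  expect_equal(scale_reaction_limited(0.24, S = 1, dT = 4.5, T_ref = 310.15),
               0.24 * (1 + 4.5 / 310.15), tolerance = 1e-12)
})

test_that("diffusion-limited scaling matches hand-evaluated values", {
  expect_identical(scale_diffusion_limited(5.4, dT = 0), 5.4)
  expect_equal(scale_diffusion_limited(5.4, dT = 4.5, T_ref = 310.15),
               5.4 * (1 + 4.5 / 310.15), tolerance = 1e-12)
  expect_equal(scale_diffusion_limited(1.05, dT = -5, T_ref = 310.15),
               1.05 * (1 - 5 / 310.15), tolerance = 1e-12)
})

test_that("both laws are linear and strictly increasing in dT", {
  dT <- seq(-8, 8, by = 0.5)
  for (f in list(function(d) scale_reaction_limited(0.1, 20, d),
                 function(d) scale_diffusion_limited(0.1, d))) {
    v <- vapply(dT, f, numeric(1))
    slopes <- diff(v) / diff(dT)
    expect_true(all(abs(slopes - slopes[1]) < 1e-12)) # exactly proportional
    expect_true(all(diff(v) > 0))                     # strictly increasing
  }
})

test_that("non-positive scaled rates are clamped with a warning", {
  expect_warning(out <- scale_reaction_limited(0.1, S = 20, dT = -20),
                 "clamped")
  expect_equal(out, 1e-12)
})

test_that("apply_temperature rescales the 9 rates and leaves constants bit-identical", {
  p0 <- nfkb_params()
  p32 <- apply_temperature(p0, 32)
  expect_equal(p32$k_i, 0.18 * (1 - 100 / 310.15), tolerance = 1e-12)
  expect_equal(p32$k_Nin, 5.4 * (1 - 5 / 310.15), tolerance = 1e-12)
  for (nm in c("K_I", "K_N", "N_tot", "k_A20", "IKK_tot", "A20")) {
    expect_identical(p32[[nm]], p0[[nm]])
  }
  # at the reference temperature the map is the exact identity
  expect_identical(unlist(apply_temperature(p0, 37)), unlist(p0))
})

test_that("law map must cover all rates and validate", {
  laws <- default_thermal_laws()
  expect_error(thermal_config(laws = laws[-1, ]), "cover exactly")
  bad <- laws; bad$S[bad$rate == "k_i"] <- NA
  expect_error(thermal_config(laws = bad), "S > 0")
  bad2 <- laws; bad2$law[1] <- "arrhenius"
  expect_error(thermal_config(laws = bad2), "one of")
})

test_that("defaults assign diffusion to the fast rates and S = 20 to the impactful ones", {
  laws <- default_thermal_laws()
  expect_setequal(laws$rate[laws$law == "diffusion"], c("k_Nin", "k_t", "alpha"))
  expect_setequal(laws$rate[laws$law == "reaction" & laws$S == 20],
                  c("k_Iin", "k_i", "k_p"))
  expect_setequal(laws$rate[laws$law == "reaction" & laws$S == 1],
                  c("k_tl", "gamma_m", "k_a"))
  expect_equal(sum(laws$law == "none"), 6L)
})

test_that("an all-Arrhenius variant still has period decreasing with temperature", {
  laws <- default_thermal_laws()
  laws$S[laws$law == "diffusion"] <- 1
  laws$law[laws$law == "diffusion"] <- "reaction"
  th <- thermal_config(laws = laws)
  periods <- vapply(c(32, 37, 39.5), function(Tc) {
    dominant_period(simulate_nfkb(
      forcing = forcing_protocol(temp_base = Tc), thermal = th,
      t_end = 8000))
  }, numeric(1))
  expect_true(all(diff(periods) < 0))
})
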
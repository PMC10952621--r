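test_that("IV generator follows the Boltzmann-gated ohmic model", {
  # at the half-activation voltage the open probability is exactly 1/2
  iv <- gen_iv_family(1, g_max = 10, v_half = 0, slope = 10, e_rev = -88.5,
                      noise_sd = 0, voltages = c(-40, 0, 40), seed = 1)
  expect_equal(iv$peak_current_pA[iv$voltage_mV == 0], 0.5 * 10 * 88.5)

  # zero driving force gives zero current
  iv2 <- gen_iv_family(1, g_max = 10, v_half = 0, slope = 10, e_rev = 0,
                       noise_sd = 0, voltages = c(-40, 0.0, 40), seed = 1)
  expect_equal(iv2$peak_current_pA[iv2$voltage_mV == 0], 0)

  # bit-reproducible under a fixed seed, different otherwise
  a <- gen_iv_family(3, seed = 7)
  b <- gen_iv_family(3, seed = 7)
  c <- gen_iv_family(3, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$peak_current_pA, c$peak_current_pA))

  # validation errors name the offending field
  expect_error(gen_iv_family(1, slope = -1, seed = 1), "slope")
  expect_error(gen_iv_family(1, voltages = c(0, 0, 20), seed = 1),
               "voltages")
  expect_error(gen_iv_family(1, capacitance = -5, seed = 1), "capacitance")
  expect_error(gen_iv_family(1, noise_sd = -1, seed = 1), "noise_sd")
})

test_that("noiseless IV generation round-trips through the activation fit", {
  iv <- gen_iv_family(2, v_half = 13.1, slope = 12, noise_sd = 0, seed = 7)
  fit <- fit_boltzmann_activation(conductance_curve(iv, e_rev = -88.5))
  expect_lt(abs(fit$v_half_mean - 13.1), 0.5)
  expect_lt(max(abs(fit$fits$slope - 12)), 0.01)
})

test_that("ITC generator delegates to the forward isotherm models", {
  g <- gen_itc_thermogram("one_site", n = 0.8, kd = 2.1e-6, dh = 7.6,
                          heat_noise_sd = 0, seed = 11)
  expect_equal(g$injections$heat_ucal, one_site_heats(0.8, 2.1e-6, 7.6, g))

  g2 <- gen_itc_thermogram("two_site", n = c(0.8, 1), kd = c(1e-7, 1e-5),
                           dh = c(-5, -9), heat_noise_sd = 0, seed = 11)
  expect_equal(g2$injections$heat_ucal,
               two_site_heats(c(0.8, 1), c(1e-7, 1e-5), c(-5, -9), g2))

  # identical site classes collapse to one site with summed stoichiometry
  both <- two_site_heats(c(0.6, 0.6), c(2.1e-6, 2.1e-6), c(7.6, 7.6), g)
  one <- one_site_heats(1.2, 2.1e-6, 7.6, g)
  expect_lt(max(abs(both - one)) / max(abs(one)), 1e-9)

  expect_error(gen_itc_thermogram("one_site", n = c(1, 1), seed = 1),
               "one_site")
  expect_identical(gen_itc_thermogram("one_site", seed = 5),
                   gen_itc_thermogram("one_site", seed = 5))
})

test_that("noiseless ITC round trip recovers the generating parameters", {
  g <- gen_itc_thermogram("one_site", n = 0.8, kd = 2.1e-6, dh = 7.6,
                          heat_noise_sd = 0, seed = 2)
  fit <- fit_binding(g, "one_site")
  expect_lt(abs(fit$sites$kd - 2.1e-6) / 2.1e-6, 0.01)
  expect_lt(abs(fit$sites$n - 0.8) / 0.8, 0.001)
  expect_lt(abs(fit$sites$dh - 7.6) / 7.6, 0.001)
})

test_that("generated ITC heats respect titrant mass balance", {
  g <- gen_itc_thermogram("two_site", n = c(0.8, 1), kd = c(0.6e-9, 538e-9),
                          dh = c(-7.7, -14.8), heat_noise_sd = 0, seed = 4)
  conc <- camiks:::itc_concentrations(g)
  for (i in seq_len(nrow(conc))) {
    l <- camiks:::free_ligand(conc$X_t[i], conc$M_t[i],
                              c(0.8, 1), c(0.6e-9, 538e-9))
    bound <- conc$M_t[i] * sum(c(0.8, 1) * l / (c(0.6e-9, 538e-9) + l))
    expect_lt(abs(l + bound - conc$X_t[i]) / conc$X_t[i], 1e-10)
  }
})

test_that("melt generator hits the sigmoid midpoint and round-trips", {
  mc <- gen_melt_curve(t_m = 42, slope = 3, baseline_low = 0.1,
                       baseline_high = 0.9, noise_sd = 0,
                       temps = seq(15, 90, 0.5), seed = 1)
  # 42 is on the grid: the midpoint of the plateaus
  expect_equal(mc$signal[mc$temp_C == 42], 0.5)

  fit <- fit_melt(gen_melt_curve(t_m = 42, slope = 3, noise_sd = 0,
                                 seed = 1))
  expect_lt(abs(fit$t_m - 42), 0.1)
})

test_that("melt fits recover Tm within 0.5 degC across noisy replicates", {
  errs <- vapply(1:100, function(s) {
    mc <- gen_melt_curve(t_m = 42, slope = 3, noise_sd = 0.02, seed = s)
    abs(fit_melt(mc)$t_m - 42)
  }, numeric(1))
  expect_lt(max(errs), 0.5)
})

test_that("CSP generator structures perturbation and assignment correctly", {
  flat <- gen_csp_table(shift_magnitude = 0, noise_sd = 0, seed = 1)
  expect_true(all(csp_table(flat)$delta == 0))

  tbl <- gen_csp_table(n_residues = 148, perturbed_range = c(88, 148),
                       shift_magnitude = 0.2, noise_sd = 0.005, seed = 3)
  dd <- csp_table(tbl)
  inside <- dd$delta[dd$residue >= 88]
  outside <- dd$delta[dd$residue < 88]
  expect_gt(mean(inside), mean(outside))

  un <- gen_csp_table(unassigned = c(10L, 20L), seed = 2)
  dd2 <- csp_table(un)
  expect_identical(which(dd2$delta_display == -0.1), c(10L, 20L))
  expect_true(all(is.na(dd2$delta[c(10, 20)])))

  expect_error(gen_csp_table(perturbed_range = c(0, 10), seed = 1),
               "perturbed_range")
})
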
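test_that("current density is capacitance-normalised current", {
  iv <- tibble::tibble(cell_id = "c1", voltage_mV = 100,
                       peak_current_pA = 500, capacitance_pF = 1)
  expect_equal(current_density(iv)$density_pA_pF, 500)

  two <- tibble::tibble(cell_id = c("c1", "c2"), voltage_mV = 100,
                        peak_current_pA = c(400, 552.2),
                        capacitance_pF = 1)
  sm <- current_density(two, summarise = TRUE)
  expect_equal(sm$mean_density, 476.1)
  expect_equal(sm$n_cells, 2L)
  expect_equal(sm$sem_density, stats::sd(c(400, 552.2)) / sqrt(2))

  bad <- dplyr::mutate(iv, capacitance_pF = 0)
  expect_error(current_density(bad), "capacitance")
})

test_that("conductance curves invert the generator and handle edge cases", {
  # ohmic currents give a flat normalised conductance of 1
  iv <- tibble::tibble(cell_id = "c1", voltage_mV = seq(-60, 100, 20),
                       peak_current_pA = 2 * (seq(-60, 100, 20) + 88.5),
                       capacitance_pF = 20)
  gv <- conductance_curve(iv, e_rev = -88.5)
  expect_equal(gv$g_norm, rep(1, 9))
  expect_equal(gv$g_nS, rep(2, 9))

  # noiseless Boltzmann family: g_norm equals the generating activation
  # curve normalised by its value at the top step
  iv2 <- gen_iv_family(1, v_half = 13.1, slope = 12, noise_sd = 0, seed = 1)
  gv2 <- conductance_curve(iv2, e_rev = -88.5)
  act <- 1 / (1 + exp((13.1 - gv2$voltage_mV) / 12))
  expect_equal(gv2$g_norm, act / max(act), tolerance = 1e-12)

  # points at the reversal potential are excluded with a warning
  iv3 <- dplyr::bind_rows(iv, tibble::tibble(
    cell_id = "c1", voltage_mV = -88.5, peak_current_pA = 0,
    capacitance_pF = 20))
  expect_warning(out <- conductance_curve(iv3, e_rev = -88.5),
                 "reversal")
  expect_false(any(out$voltage_mV == -88.5))
})

test_that("Boltzmann activation fits recover exact parameters", {
  for (vh in c(13.1, 41.0)) {
    iv <- gen_iv_family(1, v_half = vh, slope = if (vh > 20) 15 else 12,
                        noise_sd = 0, seed = 1)
    fit <- fit_boltzmann_activation(conductance_curve(iv))
    expect_lt(abs(fit$v_half_mean - vh), 0.01)
  }
})

test_that("the fitted Boltzmann respects its own point symmetry", {
  # the curve is invariant under (V, G) -> (2*v_half - V, 1 - G); so is
  # the fit
  v <- seq(-60, 100, 10)
  g <- 1 / (1 + exp((13.1 - v) / 12))
  f1 <- fit_boltzmann_activation(
    tibble::tibble(voltage_mV = v, g_norm = g), per_cell = FALSE)
  f2 <- fit_boltzmann_activation(
    tibble::tibble(voltage_mV = 2 * 13.1 - v, g_norm = 1 - g),
    per_cell = FALSE)
  expect_equal(f2$fits$v_half, f1$fits$v_half, tolerance = 1e-6)
  expect_equal(f2$fits$slope, f1$fits$slope, tolerance = 1e-6)
})

test_that("activation fit errors are informative", {
  flat <- tibble::tibble(voltage_mV = seq(-60, 100, 20), g_norm = 0.5)
  expect_error(fit_boltzmann_activation(flat, per_cell = FALSE), "flat")
  short <- tibble::tibble(voltage_mV = c(0, 20, 40), g_norm = c(.1, .5, .9))
  expect_error(fit_boltzmann_activation(short, per_cell = FALSE),
               "4 voltage points")
})

test_that("block fractions reproduce the measured density arithmetic", {
  expect_equal(block_fraction(476.1, 476.1)$r, 0)
  # fractions derived from the reported +100 mV densities at resting Ca2+
  tg <- cam_block_targets()
  expect_equal(tg$r[tg$variant == "D95V"], 1 - 220.5 / 476.1)
  expect_equal(tg$r[tg$variant == "N97I"], 1 - 347.0 / 476.1)
  expect_equal(tg$r[tg$variant == "D131H"], 1 - 312.9 / 476.1)
  expect_equal(round(tg$r[tg$variant == "D95V"], 4), 0.5369)

  # scale invariance and antitonicity
  expect_equal(block_fraction(220.5 * 3, 476.1 * 3)$r,
               block_fraction(220.5, 476.1)$r)
  r_seq <- block_fraction(c(100, 200, 300), 400)$r
  expect_true(all(diff(r_seq) < 0))

  # clipping and validation
  expect_equal(block_fraction(500, 476.1)$r, 0)
  expect_error(block_fraction(100, 0), "wt_density")
  expect_error(block_fraction(-5, 476.1), "variant_density")
})

test_that("V1/2 estimation is unbiased under measurement noise", {
  # additive current noise at 5% of the wild-type peak; single-cell fits
  # scatter widely (as the experimental sem does) but the Monte-Carlo mean
  # of the estimator stays within 1 mV of truth
  noise <- 0.05 * 50.6 * 188.5
  est <- vapply(1:100, function(s) {
    iv <- gen_iv_family(1, v_half = 13.1, slope = 12, noise_sd = noise,
                        seed = s)
    fit_boltzmann_activation(conductance_curve(iv))$v_half_mean
  }, numeric(1))
  expect_lt(abs(mean(est) - 13.1), 1)
})
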
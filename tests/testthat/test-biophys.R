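test_that("combined chemical-shift perturbation follows the weighting", {
  expect_equal(csp(0.1, 0), 0.1)
  expect_equal(csp(0, 1.0), 0.15)
  expect_equal(csp(0.03, 0.2), sqrt(0.03^2 + 0.03^2))

  # sign invariance
  expect_equal(csp(-0.07, -0.4), csp(0.07, 0.4))
  # triangle inequality over residue-wise sums
  d1 <- csp(0.02, 0.1)
  d2 <- csp(0.05, -0.3)
  expect_lte(csp(0.02 + 0.05, 0.1 - 0.3), d1 + d2)

  expect_true(is.na(csp(NA, 0.1)))
  expect_error(csp(c(1, 2), 1), "length")
})

test_that("the -0.1 ppm sentinel stays at the display layer", {
  peaks <- tibble::tibble(residue = 1:4, dH_ppm = c(0.1, NA, 0.2, 0),
                          dN_ppm = c(0, 0.3, NA, 0.5))
  out <- csp_table(peaks)
  expect_identical(out$assigned, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$delta_display[2:3], c(-0.1, -0.1))
  expect_true(all(is.na(out$delta[2:3])))
  # numeric aggregation over assigned residues is unaffected
  expect_equal(mean(out$delta, na.rm = TRUE), mean(csp(c(0.1, 0), c(0, 0.5))))
})

test_that("surface density implements the gated-count quotient", {
  expect_equal(surface_density(400, 50, 1000), 0.35)
  expect_equal(surface_density(0, 0, 1000), 0)
  expect_equal(surface_density(50, 100, 1000), 0)  # negative clipped
  expect_equal(surface_density(5000, 0, 1000), 1)  # clipped above
  expect_error(surface_density(10, 5, 0), "ecfp_pos")
  expect_error(surface_density(-1, 5, 10), "ecfp_af647_pos")
  # monotone in the double-positive count
  sd_seq <- surface_density(c(100, 200, 300), 50, 1000)
  expect_true(all(diff(sd_seq) > 0))
})

test_that("fraction intact normalises by the zero-protease lane", {
  lanes <- tibble::tibble(protease_conc = c(0, 0.1, 1, 10),
                          band_intensity = c(2000, 1500, 1000, 100))
  out <- fraction_intact(lanes)
  expect_equal(out$fraction_intact[1], 1)
  expect_equal(out$fraction_intact[3], 0.5)

  # synthetic exponential decay gives a monotone non-increasing curve
  decay <- tibble::tibble(protease_conc = c(0, 10^seq(-2, 1, 0.5)),
                          band_intensity = 1800 *
                            exp(-0.4 * c(0, 10^seq(-2, 1, 0.5))))
  expect_true(all(diff(fraction_intact(decay)$fraction_intact) <= 0))

  expect_error(fraction_intact(lanes[-1, ]), "reference")
})

test_that("extinction coefficients come from composition", {
  pep <- kv71_peptides()
  expect_identical(extinction_coefficient(pep[["HA"]]), 6990)
  expect_identical(extinction_coefficient(pep[["HB"]]), 2980)
  expect_identical(extinction_coefficient(pep[["CaM"]]), 2980)
  expect_identical(extinction_coefficient("AAAA"), 0)

  # additivity over concatenation (reduced protein)
  expect_equal(extinction_coefficient(paste0(pep[["HA"]], pep[["HB"]])),
               sum(extinction_coefficient(c(pep[["HA"]], pep[["HB"]]))))
  # cystine pairs only count when oxidised
  expect_equal(extinction_coefficient("CC", oxidized = TRUE), 125)
  expect_equal(extinction_coefficient("CC"), 0)
  expect_error(extinction_coefficient("AXZ"), "unknown residue")
})

test_that("melt fitting finds the transition midpoint and rejects bad input", {
  fit <- fit_melt(gen_melt_curve(t_m = 42, slope = 3, noise_sd = 0,
                                 seed = 1))
  expect_lt(abs(fit$t_m - 42), 0.01)

  # free plateaus absorb imperfect normalisation
  shifted <- gen_melt_curve(t_m = 55, slope = 4, baseline_low = 0.15,
                            baseline_high = 1.42, noise_sd = 0, seed = 1)
  fit2 <- fit_melt(shifted)
  expect_lt(abs(fit2$t_m - 55), 0.01)
  expect_equal(fit2$baseline_high, 1.42, tolerance = 1e-4)

  # reversed (folding-with-temperature) signal violates the convention
  mc <- gen_melt_curve(t_m = 42, slope = 3, noise_sd = 0, seed = 1)
  rev_mc <- tibble::tibble(temp_C = mc$temp_C, signal = rev(mc$signal))
  expect_error(fit_melt(rev_mc), "decreases")

  flat <- tibble::tibble(temp_C = 15:90, signal = 0.5)
  expect_error(fit_melt(flat), "flat")

  # transition outside the sampled window fails the range check
  outside <- gen_melt_curve(t_m = 100, slope = 3, noise_sd = 0,
                            temps = seq(15, 90, 1), seed = 1)
  expect_error(fit_melt(outside), class = "camiks_fit_error")
})
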
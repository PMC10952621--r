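test_that("one-site heats obey limiting behaviour", {
  ex <- default_itc_experiment()
  expect_equal(one_site_heats(0.8, 2.1e-6, 0, ex), rep(0, 20))

  # stoichiometric-titration limit: constant heats until the equivalence
  # point (X = n M at injection ~5-6 here), then essentially zero
  h <- one_site_heats(0.8, 1e-15, 7.6, ex)
  expect_lt(max(abs(h[1:4] - h[1])) / h[1], 0.01)
  expect_lt(max(abs(h[8:20])) / h[1], 1e-3)
})

test_that("forward isotherms agree with a brute-force equilibrium solver", {
  ex <- default_itc_experiment()
  withr::with_seed(99, {
    for (i in 1:20) {
      n <- runif(1, 0.5, 2)
      kd <- 10^runif(1, -9, -5)
      dh <- runif(1, -15, 15)
      mine <- one_site_heats(n, kd, dh, ex)
      ref <- brute_itc_heats(n, kd, dh, rep(2, 20), 50e-6, 750e-6, 200)
      expect_lt(max(abs(mine - ref)) / max(abs(ref)), 1e-9)
    }
    for (i in 1:20) {
      n <- runif(2, 0.4, 1.5)
      kd <- 10^runif(2, -9, -5)
      dh <- runif(2, -15, 15)
      mine <- two_site_heats(n, kd, dh, ex)
      ref <- brute_itc_heats(n, kd, dh, rep(2, 20), 50e-6, 750e-6, 200)
      expect_lt(max(abs(mine - ref)) / max(abs(ref)), 1e-9)
    }
  })
})

test_that("two-site model reduces to one-site in degenerate cases", {
  ex <- default_itc_experiment()
  both <- two_site_heats(c(0.9, 0.9), c(2.1e-6, 2.1e-6), c(7.6, 7.6), ex)
  one <- one_site_heats(1.8, 2.1e-6, 7.6, ex)
  expect_lt(max(abs(both - one)) / max(abs(one)), 1e-9)

  degen <- two_site_heats(c(0.8, 0), c(2.1e-6, 1e-7), c(7.6, -3), ex)
  expect_lt(max(abs(degen - one_site_heats(0.8, 2.1e-6, 7.6, ex))) /
              max(abs(degen)), 1e-9)
})

test_that("two-site heats are symmetric under site-class relabelling", {
  ex <- default_itc_experiment()
  ha <- two_site_heats(c(0.8, 1.0), c(0.6e-9, 538e-9), c(-7.7, -14.8), ex)
  hb <- two_site_heats(c(1.0, 0.8), c(538e-9, 0.6e-9), c(-14.8, -7.7), ex)
  expect_identical(ha, hb)
})

test_that("the tight-plus-weak isotherm is biphasic at the reported values", {
  ex <- default_itc_experiment()
  h <- two_site_heats(c(0.8, 1.0), c(0.6e-9, 538e-9), c(-7.7, -14.8), ex)
  conc <- camiks:::itc_concentrations(ex)
  ratio <- conc$X_t / conc$M_t
  # two transitions: heats step between plateaus near molar ratios 0.8 and
  # 1.8 (the per-event stoichiometries)
  step1 <- which.max(abs(diff(h[ratio < 1.3])))
  step2 <- which.max(abs(diff(h)) * (ratio[-1] > 1.3))
  expect_lt(abs(ratio[step1 + 1] - 0.8), 0.25)
  expect_lt(abs(ratio[step2 + 1] - 1.8), 0.35)
})

test_that("heats are invariant under splitting injections in half", {
  ex_full <- default_itc_experiment()
  ex_half <- itc_experiment(tibble::tibble(volume_ul = rep(1, 40)),
                            cell_conc = 50e-6, syringe_conc = 750e-6)
  hf <- one_site_heats(0.8, 2.1e-6, 7.6, ex_full)
  hh <- one_site_heats(0.8, 2.1e-6, 7.6, ex_half)
  paired <- hh[seq(1, 39, 2)] + hh[seq(2, 40, 2)]
  expect_lt(max(abs(paired - hf) / abs(hf)), 0.005)
})

test_that("binding fits recover noiseless parameters for both models", {
  g1 <- gen_itc_thermogram("one_site", n = 0.8, kd = 2.1e-6, dh = 7.6,
                           heat_noise_sd = 0, seed = 21)
  f1 <- fit_binding(g1, "one_site")
  expect_lt(abs(f1$sites$kd - 2.1e-6) / 2.1e-6, 0.001)

  g2 <- gen_itc_thermogram("two_site", n = c(0.8, 1.0),
                           kd = c(0.6e-9, 538e-9), dh = c(-7.7, -14.8),
                           heat_noise_sd = 0, seed = 21)
  f2 <- fit_binding(g2, "two_site")
  expect_lt(max(abs(f2$sites$kd - c(0.6e-9, 538e-9)) /
                  c(0.6e-9, 538e-9)), 0.01)
  expect_equal(f2$sites$kd, sort(f2$sites$kd))  # canonical ascending order
})

test_that("one-site fits to two-site data are visibly worse", {
  g2 <- gen_itc_thermogram("two_site", n = c(0.8, 1.0),
                           kd = c(0.6e-9, 538e-9), dh = c(-7.7, -14.8),
                           heat_noise_sd = 0, seed = 8)
  g1 <- gen_itc_thermogram("one_site", n = 0.8, kd = 2.1e-6, dh = 7.6,
                           heat_noise_sd = 0, seed = 8)
  sse_mismatch <- fit_binding(g2, "one_site")$sse
  sse_match <- fit_binding(g1, "one_site")$sse
  expect_gt(sse_mismatch, 10 * max(sse_match, 1e-12))
})

test_that("fit preconditions are enforced", {
  few <- gen_itc_thermogram("one_site", n_injections = 5, seed = 1)
  expect_error(fit_binding(few, "one_site"), "6 injections")
  some <- gen_itc_thermogram("one_site", n_injections = 10, seed = 1)
  expect_error(fit_binding(some, "two_site"), "12 injections")
  ex <- default_itc_experiment()
  expect_error(fit_binding(ex, "one_site"), "heat_ucal")
})

test_that("thermodynamic decomposition is exact and matches conventions", {
  th <- thermo_profile(2.1e-6, 7.6)
  # closure holds exactly by construction, dg = RT ln(kd) by definition
  expect_lt(max(abs(th$dg - (th$dh + th$minus_tds))), 1e-12)
  expect_equal(th$dg, 1.9872e-3 * 298.15 * log(2.1e-6))

  expect_equal(thermo_profile(1, 0)$dg, 0)  # standard-state identity
  expect_error(thermo_profile(-1, 0), "kd")

  # vectorised over site classes
  th2 <- thermo_profile(c(0.6e-9, 538e-9), c(-7.7, -14.8))
  expect_equal(nrow(th2), 2L)
  expect_true(all(th2$dg < 0))
})
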
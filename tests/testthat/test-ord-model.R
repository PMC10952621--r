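test_that("compiled and reference right-hand sides agree at random states", {
  p <- ord_params()
  for (s in random_ord_states(100)) {
    d_c <- model_rhs(s, p)$derivatives
    d_r <- camiks:::ord_rhs_reference(s, p)
    rel <- max(abs(d_c - d_r) / pmax(abs(d_r), 1e-9))
    expect_lt(rel, 1e-8)
  }
  # and for the other transmural cell types at the resting state
  for (ct in c("epi", "mid")) {
    pp <- ord_params(ct)
    s <- ord_initial_state(pp)
    expect_lt(max(abs(model_rhs(s, pp)$derivatives -
                        camiks:::ord_rhs_reference(s, pp))), 1e-10)
  }
})

test_that("the IKs block hook scales the current exactly linearly", {
  s <- ord_initial_state()
  s["v"] <- 0
  s["xs1"] <- 0.5
  s["xs2"] <- 0.3
  i_full <- model_rhs(s, ord_params(iks_scale = 1))$currents[["IKs"]]
  i_half <- model_rhs(s, ord_params(iks_scale = 0.5))$currents[["IKs"]]
  expect_equal(i_half, 0.5 * i_full)
  expect_error(ord_params(iks_scale = 0), "iks_scale")
  expect_error(ord_params(iks_scale = 1.5), "iks_scale")
})

test_that("the unstimulated membrane is stable at rest", {
  p <- ord_params()
  quiet <- pacing_protocol(cycle_length = 50000, stim_amp = 0,
                           stim_dur = 0.5, n_beats = 1)
  eq <- camiks:::ord_one_beat(ord_initial_state(), p, quiet)$state
  expect_lt(abs(model_rhs(eq, p)$derivatives[["v"]]), 1e-2)
  ten_s <- pacing_protocol(cycle_length = 10000, stim_amp = 0,
                           stim_dur = 0.5, n_beats = 1)
  drift <- camiks:::ord_one_beat(eq, p, ten_s)$state[["v"]] - eq[["v"]]
  expect_lt(abs(drift), 0.5)
})

test_that("a paced beat produces a physiological action potential", {
  res <- pace(ord_params(), pacing_protocol(n_beats = 1))
  tr <- res$trace
  expect_gt(max(tr$v_mV), 30)          # overshoot
  expect_lt(max(tr$v_mV), 50)
  expect_lt(tail(tr$v_mV, 1), -85)     # repolarised to rest
  expect_gt(max(tr$IKs), 0)            # outward IKs during the plateau
  # IKr peaks late, during phase-3 repolarisation
  t_peak_ikr <- tr$time_ms[which.max(tr$IKr)]
  expect_gt(t_peak_ikr, 100)
})

test_that("pacing is bitwise deterministic", {
  r1 <- pace(ord_params(), pacing_protocol(n_beats = 2), record_beats = 2)
  r2 <- pace(ord_params(), pacing_protocol(n_beats = 2), record_beats = 2)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$final_state, r2$final_state)
})

test_that("APD measurement matches hand-computed crossings", {
  # square AP: -80 to +20 mV held for 100 ms on a 0.05 ms grid; the 50%
  # level is crossed at the step edges (hand value 100.025 ms includes the
  # half-sample interpolation offsets)
  sq <- square_ap()
  expect_equal(apd(sq, 0.5), 100.025, tolerance = 1e-6)
  # the square shape makes the duration independent of the fraction
  expect_lt(abs(apd(sq, 0.999) - 100), 0.1)
  expect_lt(abs(apd(sq, 0.001) - 100), 0.1)

  # triangular AP: +40 to -80 over 300 ms decays at 0.4 mV/ms, so the 50%
  # level (-20 mV) is reached 150 ms after the peak; 150.5 ms from the
  # upstroke foot by hand
  expect_equal(apd(triangle_ap(), 0.5), 150.5, tolerance = 1e-6)

  # repolarisation failure raises a flagged error
  no_rep <- tibble::tibble(time_ms = seq(0, 100, 0.1),
                           v_mV = c(-80, rep(30, 1000)))
  expect_error(apd(no_rep, 0.5), class = "camiks_metric_error")
  expect_error(apd(sq, 1.5), "fraction")
})

test_that("steady-state pacing converges and restarts quickly", {
  st <- steady_state(min_beats = 5, max_beats = 100)
  expect_true(st$converged)
  expect_gt(st$apd50, 150)
  expect_lt(st$apd50, 300)
  # re-convergence from the converged state is near-immediate
  st2 <- steady_state(init = st$state, min_beats = 2, max_beats = 10)
  expect_true(st2$converged)
  expect_lte(st2$n_beats, 5)
  expect_lt(abs(st2$apd50 - st$apd50), 0.5)
})

test_that("APD50 is insensitive to a 10x tightening of solver tolerances", {
  st <- steady_state(min_beats = 5, max_beats = 40)
  a1 <- apd(camiks:::ord_one_beat(st$state, ord_params(),
                                  pacing_protocol(), record = TRUE,
                                  rtol = 1e-6, atol = 1e-8)$trace, 0.5)
  a2 <- apd(camiks:::ord_one_beat(st$state, ord_params(),
                                  pacing_protocol(), record = TRUE,
                                  rtol = 1e-7, atol = 1e-9)$trace, 0.5)
  expect_lt(abs(a1 - a2), 0.05)
})

test_that("model_rhs validates its inputs", {
  expect_error(model_rhs(1:10), "45")
  bad <- ord_initial_state()
  bad["v"] <- NaN
  expect_error(model_rhs(bad), "non-finite")
  expect_error(peak_iks(tibble::tibble(time_ms = 1, v_mV = 1)), "IKs")
})
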
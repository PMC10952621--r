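test_that("the Hill block multiplier follows its defining identities", {
  expect_equal(block_multiplier(1, 0), 1)
  expect_equal(block_multiplier(2, 2), 0.5)   # half-block at c = Kb
  expect_equal(block_multiplier(1, 3), 0.25)
  expect_error(block_multiplier(0, 1), "c")
  expect_error(block_multiplier(1, -1), "kb")
  # f stays in (0, 1]
  f <- block_multiplier(1, 10^seq(-3, 3))
  expect_true(all(f > 0 & f <= 1))
})

test_that("frozen-waveform calibration is exact", {
  base <- steady_state(min_beats = 5, max_beats = 60)
  cal <- calibrate_kb(0.5, baseline = base, feedback = "frozen")
  expect_identical(cal$f, 0.5)
  expect_equal(cal$kb, 1)             # with c = 1, f = 0.5 means kb = c
  expect_equal(cal$achieved_block, 0.5)

  zero <- calibrate_kb(0, baseline = base)
  expect_identical(zero$kb, 0)
  expect_identical(zero$f, 1)
  expect_error(calibrate_kb(1, baseline = base), "target_r")
})

test_that("closed-loop calibration hits the measured block fraction", {
  base <- steady_state(min_beats = 5, max_beats = 60)
  target <- 1 - 220.5 / 476.1         # strongest measured reduction
  cal <- calibrate_kb(target, baseline = base)
  expect_lt(abs(cal$achieved_block - target), 1e-3)
  # near-linearity diagnostic: calibrated f close to 1 - r
  expect_lt(abs(cal$f - (1 - target)), 0.05)
  # the calibrated Kb is consistent with its multiplier
  expect_equal(cal$f, block_multiplier(cal$c, cal$kb))
})

test_that("APD comparison reports exact relative-increase arithmetic", {
  base <- steady_state(min_beats = 5, max_beats = 60)
  targets <- tibble::tibble(variant = c("WT", "X"), r = c(0, 0.3))
  res <- apd_comparison(targets, baseline = base)
  expect_identical(res$kb[1], 0)
  expect_equal(res$relative_increase,
               100 * (res$apd50 - res$apd50_wt) / res$apd50_wt)
  expect_gt(res$apd50[2], res$apd50[1])
})
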
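#' Hill-type CaM block multiplier
#'
#' The CaM-dependent IKs block enters the action-potential model as the
#' multiplier \eqn{f = [c]/([c] + K_b)} applied to the IKs conductance,
#' where \eqn{[c]} is the CaM concentration term and \eqn{K_b} an arbitrary
#' block constant chosen to match an experimentally observed fractional
#' reduction in peak IKs.  \eqn{K_b = 0} gives \eqn{f = 1} (no block).
#' \eqn{[c]} is treated as a constant model parameter (default 1, arbitrary
#' units), making \eqn{f} time-independent within a run: since only the
#' achieved block is observable, only \eqn{f} is identifiable.
#'
#' @param c CaM concentration term, > 0 (arbitrary units).
#' @param kb Block constant, >= 0 (same units as `c`).
#' @return Multiplier f in (0, 1].
#' @export
block_multiplier <- function(c, kb) {
  if (any(!is.finite(c)) || any(c <= 0)) {
    abort("`c` must be positive and finite.",
          class = "camiks_validation_error")
  }
  if (any(!is.finite(kb)) || any(kb < 0)) {
    abort("`kb` must be finite and >= 0.",
          class = "camiks_validation_error")
  }
  c / (c + kb)
}

#' Calibrate the block constant against a target IKs reduction
#'
#' Finds \eqn{K_b} such that the steady-state peak IKs of the paced model is
#' reduced by `target_r` relative to the unblocked model, by bracketed
#' root finding on \eqn{K_b \ge 0} (monotone: peak IKs strictly decreases
#' with \eqn{K_b}).  The closed-loop simulation is used: each candidate is
#' re-paced to an APD50-steady state starting from the converged baseline,
#' so AP-shape feedback on IKs is included.  With
#' `feedback = "frozen"` the baseline beat's waveform is replayed instead,
#' in which case peak IKs scales exactly linearly in \eqn{f} and the
#' calibration is exact in one step.
#'
#' @param target_r Target fractional reduction of peak IKs, in \[0, 1).
#' @param params,protocol Model and pacing configuration.
#' @param baseline A [steady_state()] result for the unblocked model; if
#'   missing it is computed (reuse it across calibrations).
#' @param c CaM concentration term (arbitrary units, default 1).
#' @param tol Absolute tolerance on the achieved block (default 1e-3).
#' @param feedback `"closed_loop"` (default) or `"frozen"`.
#' @param recal_beats Beats of re-pacing per candidate Kb (warm restart
#'   from the converged baseline state).
#' @return Tibble (`block_spec`): `c`, `kb`, `f`, `target_r`,
#'   `achieved_block`, `peak_iks`, `peak_iks_unblocked`.
#' @export
calibrate_kb <- function(target_r, params = ord_params(),
                         protocol = pacing_protocol(), baseline = NULL,
                         c = 1, tol = 1e-3,
                         feedback = c("closed_loop", "frozen"),
                         recal_beats = 40) {
  feedback <- match.arg(feedback)
  check_non_negative(target_r, "target_r")
  if (target_r >= 1) {
    abort("`target_r` must be below 1 (complete block is not attainable).",
          class = "camiks_validation_error")
  }
  check_positive(c, "c")

  if (is.null(baseline)) {
    baseline <- steady_state(params, protocol)
  }
  peak0 <- peak_iks(baseline$last_beat)

  spec <- function(kb, f, peak) {
    tibble(c = c, kb = kb, f = f, target_r = target_r,
           achieved_block = 1 - peak / peak0,
           peak_iks = peak, peak_iks_unblocked = peak0)
  }
  if (target_r == 0) {
    return(spec(0, 1, peak0))
  }
  if (feedback == "frozen") {
    # replaying a fixed waveform, IKs (hence its peak) is proportional to f
    f <- 1 - target_r
    return(spec(c * (1 / f - 1), f, peak0 * f))
  }

  peak_at_f <- function(f) {
    p <- ord_params(params$cell_type, iks_scale = f)
    st <- steady_state(p, protocol, init = baseline$state,
                       min_beats = 2, max_beats = recal_beats)
    peak_iks(st$last_beat)
  }
  # achieved block minus target, as a function of f = c/(c+kb)
  g <- function(f) (1 - peak_at_f(f) / peak0) - target_r

  # bracket in f: block 0 at f=1, approaches 1 as f -> 0
  lo_f <- 1
  hi_f <- 1 - target_r            # near-linear response: good first bracket
  g_hi <- g(hi_f)
  it <- 0
  while (g_hi < 0 && it < 10) {   # not enough block yet: push f down
    hi_f <- hi_f * 0.8
    g_hi <- g(hi_f)
    it <- it + 1
  }
  if (g_hi < 0) {
    abort(sprintf(
      "could not bracket the target block %.3f (achieved %.3f at f = %.3f).",
      target_r, g_hi + target_r, hi_f),
      class = "camiks_calibration_error")
  }
  root <- uniroot(g, lower = hi_f, upper = lo_f, f.upper = -target_r,
                  f.lower = g_hi, tol = 1e-5)
  f_star <- root$root
  peak <- peak_at_f(f_star)
  achieved <- 1 - peak / peak0
  if (abs(achieved - target_r) > tol) {
    # refine with a secant step on the residual if uniroot stopped early
    f2 <- f_star * (1 - peak0 * (target_r - achieved) / peak)
    peak2 <- peak_at_f(f2)
    if (abs(1 - peak2 / peak0 - target_r) < abs(achieved - target_r)) {
      f_star <- f2
      peak <- peak2
      achieved <- 1 - peak / peak0
    }
  }
  if (abs(achieved - target_r) > tol) {
    abort(sprintf(
      "calibration did not reach the target block (%.4f vs %.4f, tol %g).",
      achieved, target_r, tol),
      class = "camiks_calibration_error")
  }
  spec(c * (1 / f_star - 1), f_star, peak)
}

#' APD50 comparison across block targets
#'
#' For each variant: calibrate the block constant to its fractional
#' peak-IKs reduction, pace the blocked model to an APD50-steady state
#' (warm-started from the unblocked baseline), and report APD50 and its
#' relative increase versus the unblocked model.  The default targets are
#' the measured resting-Ca2+ current-density reductions
#' ([cam_block_targets()]).
#'
#' @param block_targets Tibble with `variant` and `r` (fractional peak-IKs
#'   reduction; the WT row must have r = 0).
#' @param params,protocol Model and pacing configuration.
#' @param baseline Optional precomputed unblocked [steady_state()].
#' @param tol Calibration tolerance on the achieved block.
#' @param recal_beats Warm-restart beat cap per calibration step.
#' @return `apd_comparison` tibble: `variant`, `target_r`, `kb`, `f`,
#'   `achieved_block`, `peak_iks`, `apd50`, `apd50_wt`,
#'   `relative_increase` (percent).
#' @export
apd_comparison <- function(block_targets = cam_block_targets(),
                           params = ord_params(),
                           protocol = pacing_protocol(), baseline = NULL,
                           tol = 1e-3, recal_beats = 40) {
  block_targets <- as_tibble(block_targets)
  if (!all(c("variant", "r") %in% names(block_targets))) {
    abort("`block_targets` must have columns `variant` and `r`.",
          class = "camiks_validation_error")
  }
  if (is.null(baseline)) {
    baseline <- steady_state(params, protocol)
  }
  apd_wt <- baseline$apd50

  rows <- purrr::map(seq_len(nrow(block_targets)), function(i) {
    r_i <- block_targets$r[i]
    if (r_i == 0) {
      return(tibble(
        variant = block_targets$variant[i], target_r = 0, kb = 0, f = 1,
        achieved_block = 0, peak_iks = peak_iks(baseline$last_beat),
        apd50 = apd_wt
      ))
    }
    cal <- calibrate_kb(r_i, params, protocol, baseline = baseline,
                        tol = tol, recal_beats = recal_beats)
    p_blk <- ord_params(params$cell_type, iks_scale = cal$f)
    st <- steady_state(p_blk, protocol, init = baseline$state,
                       min_beats = 2, max_beats = recal_beats)
    tibble(
      variant = block_targets$variant[i], target_r = r_i, kb = cal$kb,
      f = cal$f, achieved_block = cal$achieved_block,
      peak_iks = cal$peak_iks, apd50 = st$apd50
    )
  })
  out <- dplyr::bind_rows(rows) |>
    mutate(
      apd50_wt = apd_wt,
      relative_increase = 100 * (.data$apd50 - apd_wt) / apd_wt
    )
  class(out) <- c("apd_comparison", class(out))
  out
}
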
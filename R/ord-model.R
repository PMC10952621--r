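# state-vector layout shared by the C and R right-hand sides
ord_state_names <- function() {
  c("v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
    "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp",
    "a", "iF", "iS", "ap", "iFp", "iSp",
    "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
    "xs1", "xs2", "xk1", "Jrelnp", "Jrelp", "CaMKt",
    "IC1", "IC2", "C1", "C2", "O", "IO")
}

ord_current_names <- function() {
  c("IKs", "IKr", "ICaL", "INaCa", "INaK", "Ito", "IK1", "INa", "INaL",
    "Istim")
}

#' Ventricular myocyte model parameters
#'
#' Parameter set for the human ventricular action-potential model: cell
#' type (transmural variant) and the IKs scaling hook through which the
#' CaM-dependent Hill block enters.  All maximal conductances are the
#' published values for the chosen cell type; the hook multiplies the IKs
#' conductance term only.
#'
#' @param cell_type `"endo"` (default), `"epi"` or `"mid"`.
#' @param iks_scale IKs conductance multiplier in (0, 1]; default 1 (no
#'   block).
#' @return An `ord_params` object.
#' @export
ord_params <- function(cell_type = c("endo", "epi", "mid"), iks_scale = 1) {
  cell_type <- match.arg(cell_type)
  check_number(iks_scale, "iks_scale")
  if (iks_scale <= 0 || iks_scale > 1) {
    abort("`iks_scale` must lie in (0, 1].",
          class = "camiks_validation_error")
  }
  structure(list(cell_type = cell_type, iks_scale = iks_scale),
            class = "ord_params")
}

# numeric parameter vector handed to the C right-hand side
ord_parm_vector <- function(params, stim_amp = 0, stim_start = 0,
                            stim_dur = 0) {
  ct <- match(params$cell_type, c("endo", "epi", "mid")) - 1
  c(ct, params$iks_scale, stim_amp, stim_start, stim_dur)
}

#' Pacing protocol
#'
#' @param cycle_length Basic cycle length (ms); default 1000.
#' @param n_beats Number of beats to deliver.
#' @param stim_amp Stimulus amplitude (uA/uF); default -80 (inward).
#' @param stim_dur Stimulus duration (ms); default 0.5.
#' @param dt_out Output sampling interval for recorded beats (ms).
#' @return A `pacing_protocol` object.
#' @export
pacing_protocol <- function(cycle_length = 1000, n_beats = 1,
                            stim_amp = -80, stim_dur = 0.5, dt_out = 0.25) {
  check_positive(cycle_length, "cycle_length")
  check_positive(stim_dur, "stim_dur")
  if (stim_dur >= cycle_length) {
    abort("`stim_dur` must be shorter than `cycle_length`.",
          class = "camiks_validation_error")
  }
  n_beats <- check_count(n_beats, "n_beats")
  check_number(stim_amp, "stim_amp")
  check_positive(dt_out, "dt_out")
  structure(list(cycle_length = cycle_length, n_beats = n_beats,
                 stim_amp = stim_amp, stim_dur = stim_dur, dt_out = dt_out),
            class = "pacing_protocol")
}

#' Resting initial state of the myocyte model
#'
#' A quiescent starting point (published resting values for the gating and
#' concentration variables; the hERG scheme starts fully in the deep closed
#' state).  Pacing to steady state from here is the supported way to obtain
#' a converged state.
#'
#' @param params An [ord_params()] object (unused fields reserved).
#' @return Named numeric state vector.
#' @export
ord_initial_state <- function(params = ord_params()) {
  setNames(
    c(-87.5, 7.268, 7.268, 144.65, 144.65, 8.6e-5, 8.49e-5, 1.61, 1.56,
      0.0074621, 0.692591, 0.692574, 0.692477, 0.448501, 0.692413,
      0.000194015, 0.496116, 0.265885,
      0.00101185, 0.999542, 0.589579, 0.000515567, 0.999542, 0.641861,
      2.43e-9, 1, 0.910671, 1, 0.99982, 0.999977, 0.00267171, 1, 1,
      0.270492, 0.0001963, 0.996801, 2.53943e-5, 3.17262e-7, 0.0124065,
      0, 0, 1, 0, 0, 0),
    ord_state_names()
  )
}

#' Evaluate the model right-hand side once
#'
#' Time derivatives of every state variable at the given state, plus the
#' instantaneous membrane currents.  This is the compiled production path;
#' an independently written pure-R transcription
#' (`camiks:::ord_rhs_reference`) backs the cross-validation tests.
#'
#' @param state Named state vector (see [ord_initial_state()]).
#' @param params An [ord_params()] object.
#' @param t Time within the beat (ms), only relevant for the stimulus
#'   window; default 0 with no stimulus.
#' @param stim_amp,stim_start,stim_dur Stimulus specification (uA/uF, ms).
#' @return List with `derivatives` (named) and `currents` (named, uA/uF).
#' @export
model_rhs <- function(state, params = ord_params(), t = 0, stim_amp = 0,
                      stim_start = 0, stim_dur = 0) {
  if (length(state) != 45L) {
    abort("`state` must have 45 elements.",
          class = "camiks_validation_error")
  }
  if (any(!is.finite(state))) {
    abort("`state` contains non-finite values.",
          class = "camiks_validation_error")
  }
  p <- ord_parm_vector(params, stim_amp, stim_start, stim_dur)
  ans <- .Call(ord_rhs_call, as.double(unname(state)), as.double(p),
               as.double(t))
  list(
    derivatives = setNames(ans[1:45], ord_state_names()),
    currents = setNames(ans[46:55], ord_current_names())
  )
}

# one lsoda call over a time segment with a fixed stimulus amplitude
ord_segment <- function(state, times, params, stim_amp, stim_dur,
                        rtol, atol) {
  p <- ord_parm_vector(params, stim_amp = stim_amp, stim_start = 0,
                       stim_dur = stim_dur)
  sol <- deSolve::lsoda(
    y = unname(state), times = times, func = "ord_derivs",
    parms = p, dllname = "camiks", initfunc = "ord_init",
    nout = 10L, outnames = ord_current_names(),
    rtol = rtol, atol = atol, maxsteps = 100000
  )
  if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[nrow(sol), -1]))) {
    abort(sprintf("ODE solver failed near t = %.2f ms.", sol[nrow(sol), 1]),
          class = "camiks_solver_error")
  }
  sol
}

# integrate one beat (stimulus segment, then free segment);
# returns list(trace = tibble or NULL, state)
ord_one_beat <- function(state, params, protocol, record = FALSE,
                         rtol = 1e-6, atol = 1e-8) {
  cl <- protocol$cycle_length
  dur <- protocol$stim_dur
  grid <- if (record) {
    unique(sort(c(seq(0, cl, by = protocol$dt_out), dur, cl)))
  } else {
    c(0, dur, cl)
  }
  t1 <- grid[grid <= dur]
  t2 <- grid[grid >= dur]
  # stimulus on over [0, dur): integrate it as its own segment so the
  # discontinuity never sits inside a solver step
  s1 <- ord_segment(state, t1, params, protocol$stim_amp, dur, rtol, atol)
  st_mid <- s1[nrow(s1), 1 + seq_len(45)]
  s2 <- ord_segment(st_mid, t2, params, 0, 0, rtol, atol)
  final <- setNames(s2[nrow(s2), 1 + seq_len(45)], ord_state_names())
  trace <- NULL
  if (record) {
    sol <- rbind(s1[-nrow(s1), , drop = FALSE], s2)
    trace <- tibble(
      time_ms = sol[, "time"],
      v_mV = sol[, 2],
      IKs = sol[, "IKs"],
      IKr = sol[, "IKr"],
      ICaL = sol[, "ICaL"],
      cai = sol[, 7]
    )
  }
  list(trace = trace, state = final)
}

#' Pace the myocyte model
#'
#' Integrates the stiff model beat by beat under the given pacing protocol
#' (stimulus delivered at the start of each cycle), recording the membrane
#' potential and key currents of the requested beats.  Deterministic given
#' tolerances: repeated runs are bitwise identical.
#'
#' @param params An [ord_params()] object.
#' @param protocol A [pacing_protocol()].
#' @param init Initial state; defaults to [ord_initial_state()].
#' @param record_beats Integer beats to record (default: the last beat).
#' @param rtol,atol Solver tolerances (relative / absolute).
#' @return List with `trace` (an `ap_trace` tibble: `beat`, `time_ms`,
#'   `v_mV`, `IKs`, `IKr`, `ICaL`, `cai`) and `final_state`.
#' @export
pace <- function(params = ord_params(), protocol = pacing_protocol(),
                 init = ord_initial_state(params),
                 record_beats = protocol$n_beats,
                 rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(protocol, "pacing_protocol"))
  state <- init
  traces <- list()
  for (beat in seq_len(protocol$n_beats)) {
    rec <- beat %in% record_beats
    res <- ord_one_beat(state, params, protocol, record = rec,
                        rtol = rtol, atol = atol)
    state <- res$state
    if (rec) {
      traces[[length(traces) + 1]] <- mutate(res$trace, beat = beat,
                                             .before = 1)
    }
  }
  trace <- if (length(traces)) dplyr::bind_rows(traces) else NULL
  if (!is.null(trace)) class(trace) <- c("ap_trace", class(trace))
  list(trace = trace, final_state = state)
}

#' Pace to an APD50-steady state
#'
#' Paces until the APD50 of consecutive beats changes by less than `tol`
#' (after at least `min_beats` beats) or `max_beats` is reached.  On
#' non-convergence at the cap a warning is issued, not an error, and the
#' final state is still returned.
#'
#' @param params An [ord_params()] object.
#' @param protocol A [pacing_protocol()]; its `n_beats` is ignored.
#' @param tol Convergence tolerance on consecutive-beat APD50 (ms).
#' @param max_beats Beat cap (default 1000).
#' @param min_beats Minimum beats before convergence may be declared.
#' @param init Initial state (defaults to rest).
#' @param rtol,atol Solver tolerances.
#' @return List with `state`, `n_beats`, `converged`, `apd50` (last beat),
#'   `apd_history`, and `last_beat` (recorded `ap_trace` of the final beat).
#' @export
steady_state <- function(params = ord_params(),
                         protocol = pacing_protocol(), tol = 0.1,
                         max_beats = 1000, min_beats = 20,
                         init = ord_initial_state(params),
                         rtol = 1e-6, atol = 1e-8) {
  check_positive(tol, "tol")
  max_beats <- check_count(max_beats, "max_beats")
  min_beats <- check_count(min_beats, "min_beats")
  state <- init
  apd_prev <- NA_real_
  apd_hist <- numeric(0)
  converged <- FALSE
  last <- NULL
  for (beat in seq_len(max_beats)) {
    res <- ord_one_beat(state, params, protocol, record = TRUE,
                        rtol = rtol, atol = atol)
    state <- res$state
    apd_now <- tryCatch(apd(res$trace, 0.5), error = function(e) NA_real_)
    apd_hist <- c(apd_hist, apd_now)
    last <- res$trace
    if (beat >= min_beats && is.finite(apd_now) && is.finite(apd_prev) &&
        abs(apd_now - apd_prev) < tol) {
      converged <- TRUE
      break
    }
    apd_prev <- apd_now
  }
  if (!converged) {
    warn(sprintf(
      "APD50 not steady to %.3g ms after %d beats (last change %.3g ms).",
      tol, length(apd_hist),
      abs(utils::tail(apd_hist, 1) - utils::tail(apd_hist, 2)[1])))
  }
  last <- mutate(last, beat = length(apd_hist), .before = 1)
  class(last) <- c("ap_trace", class(last))
  list(state = state, n_beats = length(apd_hist), converged = converged,
       apd50 = utils::tail(apd_hist, 1), apd_history = apd_hist,
       last_beat = last)
}

#' Action-potential duration at a repolarization fraction
#'
#' Amplitude is the peak potential minus the pre-stimulus diastolic
#' potential (the first sample of the beat); the duration runs from the
#' time of maximum upstroke velocity to the first subsequent downward
#' crossing of `V_peak - fraction * amplitude`, with linear interpolation
#' between samples.
#'
#' @param trace A single-beat trace with `time_ms` and `v_mV`.
#' @param fraction Repolarization fraction in (0, 1); 0.5 gives APD50.
#' @return Duration (ms).
#' @export
apd <- function(trace, fraction = 0.5) {
  check_number(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) {
    abort("`fraction` must lie strictly between 0 and 1.",
          class = "camiks_validation_error")
  }
  trace <- as_tibble(trace)
  if ("beat" %in% names(trace) && dplyr::n_distinct(trace$beat) > 1) {
    abort("`trace` must contain a single beat.",
          class = "camiks_validation_error")
  }
  t <- trace$time_ms
  v <- trace$v_mV
  v_dia <- v[1]
  i_peak <- which.max(v)
  v_peak <- v[i_peak]
  amp <- v_peak - v_dia
  if (amp < 10) {
    abort("no action potential in trace (amplitude < 10 mV).",
          class = "camiks_metric_error")
  }
  dvdt <- diff(v) / diff(t)
  i_up <- which.max(dvdt)
  t_up <- t[i_up]                      # time of maximum upstroke velocity
  v_level <- v_peak - fraction * amp
  after <- which(seq_along(v) > i_peak & v <= v_level)
  if (!length(after)) {
    abort(sprintf(
      "repolarization failure: V never crosses %.1f mV before end of beat.",
      v_level), class = "camiks_metric_error")
  }
  i2 <- after[1]
  i1 <- i2 - 1
  t_cross <- t[i1] + (t[i2] - t[i1]) * (v[i1] - v_level) / (v[i1] - v[i2])
  t_cross - t_up
}

#' Peak IKs over a beat
#'
#' @param trace A recorded beat carrying an `IKs` column (uA/uF).
#' @return Maximum IKs (uA/uF).
#' @export
peak_iks <- function(trace) {
  trace <- as_tibble(trace)
  if (!"IKs" %in% names(trace)) {
    abort("`trace` carries no IKs samples.",
          class = "camiks_validation_error")
  }
  max(trace$IKs)
}
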
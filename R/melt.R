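#' Fit a thermal melt curve
#'
#' Least-squares Boltzmann sigmoid
#' \eqn{s(T) = b_{lo} + (b_{hi} - b_{lo})/(1 + \exp((T_m - T)/k))}
#' with free plateaus, so imperfectly normalised data are handled; the
#' melting temperature is the midpoint parameter (the half-maximal response
#' of the unfolding transition).  The fit expects an unfolding signal that
#' increases with temperature (normalise a decreasing ellipticity trace
#' before fitting); flat input, a decreasing trend, or a fitted midpoint
#' outside the sampled range are errors.
#'
#' @param curve Tibble with `temp_C` (strictly increasing) and `signal`.
#' @return A `melt_fit` object with `t_m`, `slope`, `baseline_low`,
#'   `baseline_high`, `sse` and the data; see [tidy.melt_fit()].
#' @export
fit_melt <- function(curve) {
  curve <- as_tibble(curve)
  if (!all(c("temp_C", "signal") %in% names(curve))) {
    abort("`curve` must have columns `temp_C` and `signal`.",
          class = "camiks_validation_error")
  }
  check_increasing(curve$temp_C, "temp_C")
  if (nrow(curve) < 6L) {
    abort("need at least 6 temperature points.",
          class = "camiks_validation_error")
  }
  s <- curve$signal
  temp <- curve$temp_C
  if (diff(range(s)) < 1e-12 * max(abs(s), 1e-30)) {
    abort("signal is flat; no unfolding transition to fit.",
          class = "camiks_fit_error")
  }
  if (stats::cor(temp, s) < 0) {
    abort(paste0("signal decreases with temperature; fit_melt expects a ",
                 "normalised unfolding signal that increases through the ",
                 "transition."),
          class = "camiks_fit_error")
  }
  half <- min(s) + diff(range(s)) / 2
  t0 <- stats::approx(s, temp, xout = half, ties = mean)$y
  if (!is.finite(t0)) t0 <- stats::median(temp)
  model <- function(par) {
    par[1] + (par[2] - par[1]) / (1 + exp((par[3] - temp) / par[4]))
  }
  fit <- minpack.lm::nls.lm(
    par = c(b_lo = min(s), b_hi = max(s), t_m = t0, k = 3),
    fn = function(par) s - model(par),
    lower = c(-Inf, -Inf, -Inf, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  if (fit$info %in% c(0, 9)) {
    abort("melt fit failed to converge.", class = "camiks_fit_error")
  }
  cf <- fit$par
  if (cf[["t_m"]] < min(temp) || cf[["t_m"]] > max(temp)) {
    abort(sprintf(
      "fitted melting temperature %.1f C lies outside the sampled range [%g, %g].",
      cf[["t_m"]], min(temp), max(temp)),
      class = "camiks_fit_error")
  }
  structure(
    list(t_m = cf[["t_m"]], slope = cf[["k"]],
         baseline_low = cf[["b_lo"]], baseline_high = cf[["b_hi"]],
         sse = fit$deviance, data = curve,
         fitted = model(cf)),
    class = "melt_fit"
  )
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("<melt_fit> Tm = %.2f C, width %.2f C, SSE %.3g\n",
              x$t_m, x$slope, x$sse))
  invisible(x)
}

#' Tidy a melt fit
#' @param x A `melt_fit`.
#' @param ... Unused.
#' @export
tidy.melt_fit <- function(x, ...) {
  tibble(t_m = x$t_m, slope = x$slope, baseline_low = x$baseline_low,
         baseline_high = x$baseline_high)
}

#' @rdname tidy.melt_fit
#' @export
glance.melt_fit <- function(x, ...) {
  tibble(t_m = x$t_m, sse = x$sse, n_points = nrow(x$data))
}
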
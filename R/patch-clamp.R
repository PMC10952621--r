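#' Current density from an I-V family
#'
#' Divides each peak current by the cell's membrane capacitance.  With
#' `summarise = TRUE` the per-cell densities are aggregated to mean and
#' standard error per voltage, the form in which current densities at
#' +100 mV are usually reported.
#'
#' @param iv Tibble with `cell_id`, `voltage_mV`, `peak_current_pA`,
#'   `capacitance_pF` (the [gen_iv_family()] layout).
#' @param summarise Aggregate across cells? Default `FALSE` (per-cell rows).
#' @return Tibble of per-cell densities (`density_pA_pF`), or per-voltage
#'   `mean_density`, `sem_density`, `n_cells` when summarised.
#' @export
current_density <- function(iv, summarise = FALSE) {
  iv <- as_tibble(iv)
  need <- c("cell_id", "voltage_mV", "peak_current_pA", "capacitance_pF")
  if (!all(need %in% names(iv))) {
    abort(paste0("`iv` must have columns: ", paste(need, collapse = ", ")),
          class = "camiks_validation_error")
  }
  if (any(!is.finite(iv$capacitance_pF)) || any(iv$capacitance_pF <= 0)) {
    abort("`capacitance_pF` must be positive for every cell.",
          class = "camiks_validation_error")
  }
  dens <- iv |>
    mutate(density_pA_pF = .data$peak_current_pA / .data$capacitance_pF)
  if (!summarise) {
    return(dens |> select(dplyr::all_of(c("cell_id", "voltage_mV",
                                          "density_pA_pF"))))
  }
  dens |>
    group_by(.data$voltage_mV) |>
    summarise(
      mean_density = mean(.data$density_pA_pF),
      sem_density = stats::sd(.data$density_pA_pF) / sqrt(dplyr::n()),
      n_cells = dplyr::n(),
      .groups = "drop"
    )
}

#' Normalised conductance from peak currents
#'
#' Chord conductance \eqn{G(V) = I(V) / (V - E_{rev})}, normalised per cell
#' by its maximum over the voltage ladder.  Steps at the reversal potential
#' have no driving force and are excluded with a warning.
#'
#' @param iv I-V family tibble (see [current_density()]).
#' @param e_rev Reversal potential (mV); defaults to the K+ Nernst potential
#'   for the recording solutions (about -88.5 mV).
#' @return Tibble with `cell_id`, `voltage_mV`, `g_nS`, `g_norm`.
#' @export
conductance_curve <- function(iv, e_rev = -88.5) {
  iv <- as_tibble(iv)
  check_number(e_rev, "e_rev")
  at_rev <- iv$voltage_mV == e_rev
  if (any(at_rev)) {
    warn(sprintf(
      "%d point(s) at the reversal potential excluded (zero driving force).",
      sum(at_rev)))
    iv <- iv[!at_rev, ]
  }
  iv |>
    mutate(g_nS = .data$peak_current_pA / (.data$voltage_mV - e_rev)) |>
    group_by(.data$cell_id) |>
    mutate(g_norm = .data$g_nS / max(.data$g_nS)) |>
    ungroup() |>
    select(dplyr::all_of(c("cell_id", "voltage_mV", "g_nS", "g_norm")))
}

# single-cell Boltzmann fit on (voltage, g) with free amplitude:
# g = gmax / (1 + exp((v_half - V)/slope))
fit_boltzmann_one <- function(voltage, g, init_slope = 15) {
  if (length(voltage) < 4L) {
    abort("need at least 4 voltage points spanning the activation range.",
          class = "camiks_validation_error")
  }
  if (diff(range(g)) < 1e-10 * max(abs(g), 1e-30)) {
    abort("conductance data are flat; no activation transition to fit.",
          class = "camiks_fit_error")
  }
  half <- min(g) + diff(range(g)) / 2
  v0 <- stats::approx(g, voltage, xout = half, ties = mean)$y
  if (!is.finite(v0)) v0 <- stats::median(voltage)
  v0 <- min(max(v0, min(voltage)), max(voltage))
  start <- c(gmax = max(g), v_half = v0, slope = init_slope)
  res_fun <- function(par) {
    g - par[1] / (1 + exp((par[2] - voltage) / par[3]))
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = res_fun,
    lower = c(1e-9, -Inf, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  if (fit$info %in% c(0, 9)) {
    abort(paste0(
      "Boltzmann activation fit failed to converge; initial guesses gmax=",
      signif(start[1], 4), ", v_half=", signif(start[2], 4), ", slope=",
      signif(start[3], 4), "; data span [", signif(min(g), 3), ", ",
      signif(max(g), 3), "]."),
      class = "camiks_fit_error")
  }
  cf <- fit$par
  tibble(v_half = cf[["v_half"]], slope = cf[["slope"]], gmax = cf[["gmax"]],
         residual = fit$deviance)
}

#' Boltzmann activation fit of normalised conductance
#'
#' Fits \eqn{G/G_{max} = g_{max} / (1 + \exp((V_{1/2} - V)/k))} by
#' Levenberg-Marquardt, per cell by default (V1/2 is then summarised across
#' cells, matching the practice of fitting individual activation curves), or
#' pooled over all points.  The amplitude is left free so that
#' normalisation by the largest sampled conductance (which sits slightly
#' below the true asymptote) does not bias V1/2.  Initial guesses: the
#' voltage at the empirical half-maximum, slope 15 mV.
#'
#' @param gv Tibble with `voltage_mV` and `g_norm` (and `cell_id` for
#'   per-cell fits), e.g. from [conductance_curve()].
#' @param per_cell Fit each cell separately? Default `TRUE` when a
#'   `cell_id` column is present.
#' @return An `activation_fit` object with per-fit parameters; see
#'   [tidy.activation_fit()].
#' @export
fit_boltzmann_activation <- function(gv, per_cell = "cell_id" %in% names(gv)) {
  gv <- as_tibble(gv)
  if (!all(c("voltage_mV", "g_norm") %in% names(gv))) {
    abort("`gv` must have columns `voltage_mV` and `g_norm`.",
          class = "camiks_validation_error")
  }
  fits <- if (per_cell) {
    gv |>
      group_by(.data$cell_id) |>
      dplyr::group_modify(~ fit_boltzmann_one(.x$voltage_mV, .x$g_norm)) |>
      ungroup()
  } else {
    fit_boltzmann_one(gv$voltage_mV, gv$g_norm) |>
      mutate(cell_id = "pooled", .before = 1)
  }
  structure(
    list(fits = fits, per_cell = per_cell,
         v_half_mean = mean(fits$v_half),
         v_half_sem = if (nrow(fits) > 1)
           stats::sd(fits$v_half) / sqrt(nrow(fits)) else NA_real_),
    class = "activation_fit"
  )
}

#' @export
print.activation_fit <- function(x, ...) {
  cat(sprintf("<activation_fit> %d fit(s); V1/2 = %.2f mV%s\n",
              nrow(x$fits), x$v_half_mean,
              if (is.na(x$v_half_sem)) ""
              else sprintf(" +/- %.2f (sem)", x$v_half_sem)))
  print(x$fits)
  invisible(x)
}

#' Tidy / summarise an activation fit
#' @param x An `activation_fit`.
#' @param ... Unused.
#' @export
tidy.activation_fit <- function(x, ...) x$fits

#' @rdname tidy.activation_fit
#' @export
glance.activation_fit <- function(x, ...) {
  tibble(n_fits = nrow(x$fits), v_half_mean = x$v_half_mean,
         v_half_sem = x$v_half_sem, slope_mean = mean(x$fits$slope))
}

#' Fractional current-density block relative to wild type
#'
#' \eqn{r = 1 - I_{variant}/I_{WT}}, clipped at zero when the variant
#' exceeds wild type.  This fraction is the calibration target for the
#' simulated Hill block of IKs.  Scale-invariant in the pair of densities
#' and antitone in the variant density.
#'
#' @param variant_density Variant current density (pA/pF), >= 0; vectorised.
#' @param wt_density Wild-type current density (pA/pF), > 0.
#' @param variant Optional variant labels.
#' @param condition Optional condition label (e.g. Ca2+ level).
#' @return Tibble with `variant`, `condition`, `r`.
#' @export
block_fraction <- function(variant_density, wt_density, variant = NULL,
                           condition = NULL) {
  check_positive(wt_density, "wt_density")
  if (any(!is.finite(variant_density)) || any(variant_density < 0)) {
    abort("`variant_density` must be finite and >= 0.",
          class = "camiks_validation_error")
  }
  tibble(
    variant = variant %||% paste0("variant_", seq_along(variant_density)),
    condition = condition %||% NA_character_,
    r = pmax(0, 1 - variant_density / wt_density)
  )
}

#' Measured IKs current densities for CaM variants
#'
#' Reported mean current densities at +100 mV (pA/pF) for wild-type
#' calmodulin and the long-QT variants D95V, N97I and D131H at resting
#' (100 nM) and high (1 uM) free Ca2+.  These printed means are the inputs
#' from which the simulation block targets are derived.
#'
#' @return Tibble with `variant`, `condition`, `density_pA_pF`, `v_half_mV`.
#' @export
cam_variant_densities <- function() {
  tibble(
    variant = rep(c("WT", "D95V", "N97I", "D131H"), 2),
    condition = rep(c("resting_100nM", "high_1uM"), each = 4),
    density_pA_pF = c(476.1, 220.5, 347.0, 312.9,
                      505.4, 341.1, 331.9, 415.9),
    v_half_mV = c(13.1, 34.4, 14.9, 41.0,
                  22.2, 31.6, 22.5, 32.1)
  )
}

#' Default simulation block targets from measured densities
#'
#' Fractional peak-IKs reductions for each variant relative to wild type,
#' computed with [block_fraction()] from the measured current densities.
#' The resting-Ca2+ (100 nM) condition is the default because its variant
#' ordering (D95V > D131H > N97I) matches the reported ordering of
#' action-potential prolongation; the high-Ca2+ targets remain available.
#'
#' @param condition `"resting_100nM"` (default) or `"high_1uM"`.
#' @return Tibble with `variant`, `condition`, `r` (WT row has r = 0).
#' @export
cam_block_targets <- function(condition = c("resting_100nM", "high_1uM")) {
  condition <- match.arg(condition)
  dens <- cam_variant_densities() |> filter(.data$condition == !!condition)
  wt <- dens$density_pA_pF[dens$variant == "WT"]
  block_fraction(dens$density_pA_pF, wt, variant = dens$variant,
                 condition = condition)
}
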
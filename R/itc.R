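#' Construct an ITC experiment
#'
#' Bundles the injection schedule and measured per-injection heats with the
#' cell/syringe concentrations, active cell volume and temperature needed by
#' the isotherm models.  Concentration corrections for the liquid displaced
#' from an overfilled cell use the standard perfusion approximation: after a
#' cumulative injected volume \eqn{v}, cell-resident species are scaled by
#' \eqn{(1 - v/2V_0)/(1 + v/2V_0)} and the total titrant concentration is
#' \eqn{X_s (v/V_0)/(1 + v/2V_0)}.  The synthetic generator and the fitting
#' routines share this single convention.
#'
#' @param injections Data frame with columns `volume_ul` and (optionally)
#'   `heat_ucal`; one row per injection in order.
#' @param cell_conc Macromolecule concentration in the cell (molar).
#' @param syringe_conc Titrant concentration in the syringe (molar).
#' @param cell_volume Active cell volume (microlitre). MicroCal iTC200-class
#'   instruments have an active volume near 200 ul, the default here.
#' @param temperature Experiment temperature (kelvin); default 298.15 K (25 C).
#'
#' @return An object of class `itc_experiment`.
#' @export
itc_experiment <- function(injections, cell_conc, syringe_conc,
                           cell_volume = 200, temperature = 298.15) {
  check_positive(cell_conc, "cell_conc")
  check_positive(syringe_conc, "syringe_conc")
  check_positive(cell_volume, "cell_volume")
  check_positive(temperature, "temperature")
  injections <- as_tibble(injections)
  if (!"volume_ul" %in% names(injections) || nrow(injections) < 1L) {
    abort("`injections` needs at least one row and a `volume_ul` column.",
          class = "camiks_validation_error")
  }
  if (any(injections$volume_ul <= 0)) {
    abort("`volume_ul` entries must all be positive.",
          class = "camiks_validation_error")
  }
  injections$injection <- seq_len(nrow(injections))
  structure(
    list(
      injections = injections[, c("injection", "volume_ul",
                                  intersect("heat_ucal", names(injections)))],
      cell_conc = cell_conc,
      syringe_conc = syringe_conc,
      cell_volume = cell_volume,
      temperature = temperature
    ),
    class = "itc_experiment"
  )
}

#' @export
print.itc_experiment <- function(x, ...) {
  cat(sprintf(
    "<itc_experiment> %d injections | cell %.3g M, syringe %.3g M, V0 %.0f ul, T %.2f K\n",
    nrow(x$injections), x$cell_conc, x$syringe_conc, x$cell_volume,
    x$temperature))
  print(x$injections, ...)
  invisible(x)
}

# total (displacement-corrected) concentrations after each injection:
# returns tibble(injection, volume_ul, M_t, X_t, dv_cum)
itc_concentrations <- function(experiment) {
  vol <- experiment$injections$volume_ul
  dv <- cumsum(vol)
  v0 <- experiment$cell_volume
  f_cell <- (1 - dv / (2 * v0)) / (1 + dv / (2 * v0))
  tibble(
    injection = seq_along(vol),
    volume_ul = vol,
    M_t = experiment$cell_conc * f_cell,
    X_t = experiment$syringe_conc * (dv / v0) / (1 + dv / (2 * v0))
  )
}

# cumulative heat (ucal) -> differential per-injection heats with the
# displaced-volume correction  dQ_i = Q_i - Q_{i-1} + (dV_i/V0)(Q_i+Q_{i-1})/2
differential_heats <- function(q_cum, volumes, cell_volume) {
  q_prev <- c(0, q_cum[-length(q_cum)])
  q_cum - q_prev + (volumes / cell_volume) * (q_cum + q_prev) / 2
}

#' Per-injection heats for a single-site binding isotherm
#'
#' Computes the differential heats of a titration with one class of
#' independent sites.  After injection \eqn{i} the bound fraction solves the
#' standard one-site quadratic in total macromolecule \eqn{M_i}, total
#' titrant \eqn{X_i} and \eqn{K_d}; cumulative heat is
#' \eqn{Q_i = n \Theta_i M_i \Delta H V_0} and the reported heat carries the
#' displaced-volume correction.
#'
#' @param n Stoichiometry (sites per macromolecule).
#' @param kd Dissociation constant (molar).
#' @param dh Binding enthalpy (kcal/mol).
#' @param experiment An [itc_experiment()].
#' @return Numeric vector of per-injection heats (ucal).
#' @export
one_site_heats <- function(n, kd, dh, experiment) {
  check_positive(n, "n")
  check_positive(kd, "kd")
  check_number(dh, "dh")
  stopifnot(inherits(experiment, "itc_experiment"))
  conc <- itc_concentrations(experiment)
  nm <- n * conc$M_t
  b <- 1 + conc$X_t / nm + kd / nm
  theta <- (b - sqrt(b * b - 4 * conc$X_t / nm)) / 2
  q_cum <- n * theta * conc$M_t * dh * experiment$cell_volume * 1e3
  differential_heats(q_cum, conc$volume_ul, experiment$cell_volume)
}

# free-ligand concentration for a set of independent site classes, by
# bracketed root finding on the mass balance (monotone in L)
free_ligand <- function(x_t, m_t, n, kd, tol = 1e-12) {
  mass <- function(l) l + m_t * sum(n * l / (kd + l)) - x_t
  if (x_t <= 0) return(0)
  l <- uniroot(mass, lower = 0, upper = x_t,
               tol = tol * max(x_t, 1e-12))$root
  # Newton polish to machine precision (mass balance to ~1e-15 relative)
  for (i in 1:4) {
    fx <- mass(l)
    dfx <- 1 + m_t * sum(n * kd / (kd + l)^2)
    l_new <- l - fx / dfx
    if (!is.finite(l_new) || l_new < 0) break
    l <- l_new
    if (abs(fx) < 1e-14 * x_t) break
  }
  l
}

#' Per-injection heats for two independent site classes
#'
#' Free titrant after each injection solves the two-site mass balance
#' \eqn{X = L + M \sum_j n_j L/(K_{d,j} + L)} by bracketed root finding;
#' cumulative heat sums the per-class occupancies weighted by their
#' enthalpies.  With both classes identical this reduces exactly to
#' [one_site_heats()] with the stoichiometries summed.
#'
#' @param n,kd,dh Numeric vectors of length 2: per-class stoichiometry,
#'   dissociation constant (molar) and enthalpy (kcal/mol).
#' @param experiment An [itc_experiment()].
#' @return Numeric vector of per-injection heats (ucal).
#' @export
two_site_heats <- function(n, kd, dh, experiment) {
  if (length(n) != 2L || length(kd) != 2L || length(dh) != 2L) {
    abort("`n`, `kd` and `dh` must each have two entries (one per site class).",
          class = "camiks_validation_error")
  }
  for (i in 1:2) {
    check_non_negative(n[i], sprintf("n[%d]", i))
    check_positive(kd[i], sprintf("kd[%d]", i))
    check_number(dh[i], sprintf("dh[%d]", i))
  }
  stopifnot(inherits(experiment, "itc_experiment"))
  conc <- itc_concentrations(experiment)
  q_cum <- vapply(seq_len(nrow(conc)), function(i) {
    l <- free_ligand(conc$X_t[i], conc$M_t[i], n, kd)
    conc$M_t[i] * sum(n * dh * l / (kd + l)) *
      experiment$cell_volume * 1e3
  }, numeric(1))
  differential_heats(q_cum, conc$volume_ul, experiment$cell_volume)
}

#' Fit a binding model to ITC heats
#'
#' Least-squares fit of the measured per-injection heats to the one-site or
#' independent two-site isotherm, by Levenberg-Marquardt on
#' \eqn{(\log n, \log_{10} K_d, \Delta H)} per site class.  The two-site fit
#' is initialised from the one-site fit plus a second class at 100-fold
#' weaker affinity, matching the tight-plus-weak structure of biphasic
#' isotherms; fitted site classes are reported in ascending \eqn{K_d}.
#'
#' @param experiment An [itc_experiment()] whose `injections` carry
#'   `heat_ucal`.
#' @param model `"one_site"` or `"two_site"`.
#' @param init Optional named list of starting values
#'   (`n`, `kd`, `dh`, vectors for two-site).
#' @param weights Optional per-injection weights (default equal).
#' @return A `binding_fit` object; see [tidy.binding_fit()].
#' @export
fit_binding <- function(experiment, model = c("one_site", "two_site"),
                        init = NULL, weights = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(experiment, "itc_experiment"))
  if (!"heat_ucal" %in% names(experiment$injections)) {
    abort("`experiment` carries no measured heats (`heat_ucal`).",
          class = "camiks_validation_error")
  }
  heats <- experiment$injections$heat_ucal
  n_inj <- length(heats)
  min_inj <- if (model == "one_site") 6L else 12L
  if (n_inj < min_inj) {
    abort(sprintf("`%s` fits need at least %d injections (have %d).",
                  model, min_inj, n_inj),
          class = "camiks_validation_error")
  }
  weights <- weights %||% rep(1, n_inj)

  n_classes <- if (model == "one_site") 1L else 2L

  predict_heats <- function(par) {
    n <- exp(par[seq_len(n_classes)])
    kd <- 10^par[n_classes + seq_len(n_classes)]
    dh <- par[2 * n_classes + seq_len(n_classes)]
    if (model == "one_site") {
      one_site_heats(n, kd, dh, experiment)
    } else {
      two_site_heats(n, kd, dh, experiment)
    }
  }
  res_fun <- function(par) sqrt(weights) * (heats - predict_heats(par))

  run_lm <- function(par0) {
    tryCatch(
      minpack.lm::nls.lm(
        par = par0, fn = res_fun,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
  }
  starts <- if (is.null(init)) {
    binding_fit_starts(experiment, model)
  } else {
    list(c(log(init$n), log10(init$kd), init$dh))
  }
  fits <- purrr::map(starts, run_lm)
  fits <- purrr::keep(fits, ~ !is.null(.x) && !(.x$info %in% c(0, 9)))
  if (!length(fits)) {
    abort("binding fit did not converge from any starting point.",
          class = "camiks_fit_error")
  }
  fit <- fits[[which.min(purrr::map_dbl(fits, "deviance"))]]
  par <- fit$par
  sites <- tibble(
    site = seq_len(n_classes),
    n = exp(par[seq_len(n_classes)]),
    kd = 10^par[n_classes + seq_len(n_classes)],
    dh = par[2 * n_classes + seq_len(n_classes)]
  )
  ord <- order(sites$kd)
  sites <- sites[ord, ]
  sites$site <- seq_len(n_classes)
  fitted <- predict_heats(par)
  structure(
    list(
      sites = sites,
      model = model,
      experiment = experiment,
      fitted = fitted,
      residuals = heats - fitted,
      sse = sum(weights * (heats - fitted)^2),
      deviance = fit$deviance,
      info = fit$info,
      hessian = fit$hessian
    ),
    class = "binding_fit"
  )
}

# deterministic starting points (log n, log10 kd, dh per class).
# one_site: a saturation heuristic on the total heat.  two_site: anchored at
# the one-site fit, with a small fixed grid of affinity splits around it --
# biphasic tight-plus-weak isotherms routinely defeat a single start because
# the tight site sits far outside the identifiable c-value window.
binding_fit_starts <- function(experiment, model) {
  heats <- experiment$injections$heat_ucal
  m0 <- experiment$cell_conc
  v0 <- experiment$cell_volume
  q_tot <- sum(heats)
  dh0 <- q_tot / (m0 * v0 * 1e3)       # assumes n ~ 1, full saturation
  if (!is.finite(dh0) || dh0 == 0) dh0 <- sign(q_tot + 1e-12)
  if (model == "one_site") {
    return(list(c(log(1), log10(m0 / 10), dh0)))
  }
  one <- fit_binding(experiment, "one_site")
  n1 <- one$sites$n
  kd1 <- one$sites$kd
  dh1 <- one$sites$dh
  splits <- expand.grid(f1 = c(1, 1e-2, 1e-4), f2 = c(1, 1e2))
  purrr::map(seq_len(nrow(splits)), function(i) {
    c(log(c(max(n1 / 2, 0.05), max(n1 / 2, 0.05))),
      log10(c(kd1 * splits$f1[i], kd1 * splits$f2[i])),
      c(dh1, dh1))
  })
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> %s model, SSE %.4g ucal^2\n", x$model, x$sse))
  print(x$sites)
  invisible(x)
}

#' Tidy a binding fit
#'
#' One row per site class with the fitted stoichiometry, dissociation
#' constant, enthalpy and the derived Gibbs energy and entropy term at the
#' experiment temperature.
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @export
tidy.binding_fit <- function(x, ...) {
  th <- thermo_profile(x$sites$kd, x$sites$dh, x$experiment$temperature)
  dplyr::bind_cols(x$sites, th[, c("dg", "minus_tds")])
}

#' @rdname tidy.binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(model = x$model, n_injections = length(x$residuals),
         sse = x$sse, rmse = sqrt(mean(x$residuals^2)))
}

#' Thermodynamic decomposition of a binding constant
#'
#' \eqn{\Delta G = RT \ln K_d} (with \eqn{K_d} in molar, i.e. relative to the
#' 1 M standard state), \eqn{-T\Delta S = \Delta G - \Delta H}, so that
#' \eqn{\Delta G = \Delta H + (-T\Delta S)} holds exactly by construction.
#' Uses R = 1.9872e-3 kcal/mol/K.
#'
#' @param kd Dissociation constant(s), molar.
#' @param dh Enthalpy change(s), kcal/mol.
#' @param temperature Absolute temperature (K), default 298.15.
#' @return Tibble with `kd`, `dh`, `dg`, `minus_tds`, `temperature`
#'   (energies in kcal/mol).
#' @export
thermo_profile <- function(kd, dh, temperature = 298.15) {
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    abort("`kd` must be positive and finite.",
          class = "camiks_validation_error")
  }
  check_positive(temperature, "temperature")
  dg <- R_KCAL * temperature * log(kd)
  tibble(kd = kd, dh = dh, dg = dg, minus_tds = dg - dh,
         temperature = temperature)
}
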
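#' Generate a synthetic voltage-clamp I-V family
#'
#' Emulates peak-current measurements from an IKs activation protocol:
#' step potentials from a holding potential, one peak current per step, with
#' Boltzmann-gated conductance
#' \eqn{I(V) = g_{max} (V - E_{rev}) / (1 + \exp((V_{1/2} - V)/k))}
#' plus additive Gaussian noise.  The default voltage ladder is the
#' experimental protocol (-60 to +100 mV in 20 mV steps); the default
#' conductance scale and capacitance are chosen so a wild-type-like cell has
#' a current density near 476 pA/pF at +100 mV, and the default noise is 5%
#' of that peak current.
#'
#' @param n_cells Number of cells to simulate.
#' @param g_max Maximal conductance (nS); peak current comes out in pA.
#' @param v_half Half-activation voltage (mV).
#' @param slope Boltzmann slope factor (mV), > 0.
#' @param e_rev Reversal potential (mV); the potassium Nernst potential for
#'   4 mM external / 130 mM internal K+ near room temperature is about
#'   -88.5 mV.
#' @param capacitance Membrane capacitance (pF), recycled across cells.
#' @param noise_sd Additive current noise s.d. (pA), >= 0.
#' @param voltages Step potentials (mV), strictly increasing.
#' @param seed Integer RNG seed (required; generation is bit-reproducible).
#' @return Tibble with columns `cell_id`, `voltage_mV`, `peak_current_pA`,
#'   `capacitance_pF`; generator parameters attached as the
#'   `"params"` attribute.
#' @export
gen_iv_family <- function(n_cells, g_max = 50.6, v_half = 13.1, slope = 12,
                          e_rev = -88.5, capacitance = 20, noise_sd = 475,
                          voltages = seq(-60, 100, by = 20), seed) {
  n_cells <- check_count(n_cells, "n_cells")
  check_positive(g_max, "g_max")
  check_number(v_half, "v_half")
  check_positive(slope, "slope")
  check_number(e_rev, "e_rev")
  check_non_negative(noise_sd, "noise_sd")
  check_increasing(voltages, "voltages")
  caps <- rep_len(capacitance, n_cells)
  if (any(caps <= 0)) {
    abort("`capacitance` must be positive.", class = "camiks_validation_error")
  }
  check_seed(seed)

  act <- 1 / (1 + exp((v_half - voltages) / slope))
  clean <- g_max * (voltages - e_rev) * act
  with_seed(seed, {
    out <- purrr::map(seq_len(n_cells), function(cell) {
      tibble(
        cell_id = sprintf("cell_%02d", cell),
        voltage_mV = voltages,
        peak_current_pA = clean + rnorm(length(voltages), sd = noise_sd),
        capacitance_pF = caps[cell]
      )
    })
    out <- dplyr::bind_rows(out)
  })
  attr(out, "params") <- list(
    g_max = g_max, v_half = v_half, slope = slope, e_rev = e_rev,
    capacitance = caps, noise_sd = noise_sd, voltages = voltages, seed = seed
  )
  out
}

#' Generate a synthetic ITC thermogram
#'
#' Draws per-injection heats from the exact forward isotherm models
#' ([one_site_heats()] / [two_site_heats()]) under the experimental
#' injection protocol (20 x 2 ul injections into ~50 uM macromolecule by
#' default) plus additive Gaussian noise, sharing the displacement-dilution
#' convention with the fitting routines so noiseless round trips are exact.
#'
#' @param model `"one_site"` or `"two_site"`.
#' @param n,kd,dh Site parameters; scalars for `one_site`, length-2 vectors
#'   for `two_site` (stoichiometry, molar dissociation constant, kcal/mol
#'   enthalpy).
#' @param cell_conc,syringe_conc Cell and syringe concentrations (molar).
#' @param cell_volume Active cell volume (ul).
#' @param n_injections Number of injections.
#' @param inj_volume Volume per injection (ul).
#' @param heat_noise_sd Heat noise s.d. (ucal), >= 0.
#' @param temperature Temperature (K).
#' @param seed Integer RNG seed.
#' @return An [itc_experiment()] whose injections carry `heat_ucal`; true
#'   parameters in the `"params"` attribute.
#' @export
gen_itc_thermogram <- function(model = c("one_site", "two_site"),
                               n = 0.8, kd = 2.1e-6, dh = 7.6,
                               cell_conc = 50e-6, syringe_conc = 750e-6,
                               cell_volume = 200, n_injections = 20,
                               inj_volume = 2, heat_noise_sd = 0.1,
                               temperature = 298.15, seed) {
  model <- match.arg(model)
  n_injections <- check_count(n_injections, "n_injections")
  check_positive(inj_volume, "inj_volume")
  check_non_negative(heat_noise_sd, "heat_noise_sd")
  check_seed(seed)
  n_classes <- if (model == "one_site") 1L else 2L
  if (length(n) != n_classes || length(kd) != n_classes ||
      length(dh) != n_classes) {
    abort(sprintf("`%s` needs %d entr%s in each of `n`, `kd`, `dh`.",
                  model, n_classes, if (n_classes == 1L) "y" else "ies"),
          class = "camiks_validation_error")
  }

  exp0 <- itc_experiment(
    tibble(volume_ul = rep(inj_volume, n_injections)),
    cell_conc = cell_conc, syringe_conc = syringe_conc,
    cell_volume = cell_volume, temperature = temperature
  )
  clean <- if (model == "one_site") {
    one_site_heats(n, kd, dh, exp0)
  } else {
    two_site_heats(n, kd, dh, exp0)
  }
  heats <- with_seed(seed, clean + rnorm(n_injections, sd = heat_noise_sd))
  exp0$injections$heat_ucal <- heats
  attr(exp0, "params") <- list(model = model, n = n, kd = kd, dh = dh,
                               heat_noise_sd = heat_noise_sd, seed = seed)
  exp0
}

#' Generate a synthetic thermal melt curve
#'
#' Sigmoidal unfolding signal
#' \eqn{s(T) = b_{lo} + (b_{hi} - b_{lo}) / (1 + \exp((T_m - T)/k))}
#' plus Gaussian noise, emulating a normalised circular-dichroism melt
#' sampled in 1 degree increments from 15 to 90 C.
#'
#' @param t_m Melting temperature (C).
#' @param slope Transition width (C), > 0.
#' @param baseline_low,baseline_high Signal plateaus (folded / unfolded).
#' @param noise_sd Signal noise s.d., >= 0.
#' @param temps Sampled temperatures (C), strictly increasing.
#' @param seed Integer RNG seed.
#' @return Tibble with `temp_C`, `signal`; parameters in the `"params"`
#'   attribute.
#' @export
gen_melt_curve <- function(t_m = 42, slope = 3, baseline_low = 0,
                           baseline_high = 1, noise_sd = 0.02,
                           temps = seq(15, 90, by = 1), seed) {
  check_number(t_m, "t_m")
  check_positive(slope, "slope")
  check_number(baseline_low, "baseline_low")
  check_number(baseline_high, "baseline_high")
  check_non_negative(noise_sd, "noise_sd")
  check_increasing(temps, "temps")
  check_seed(seed)
  clean <- baseline_low +
    (baseline_high - baseline_low) / (1 + exp((t_m - temps) / slope))
  out <- with_seed(seed, tibble(
    temp_C = temps,
    signal = clean + rnorm(length(temps), sd = noise_sd)
  ))
  attr(out, "params") <- list(t_m = t_m, slope = slope,
                              baseline_low = baseline_low,
                              baseline_high = baseline_high,
                              noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a synthetic chemical-shift-perturbation peak table
#'
#' Per-residue 1H and 15N shift differences: residues inside
#' `perturbed_range` receive Gaussian draws with s.d. scaled by
#' `shift_magnitude` (15N draws scaled up by the inverse of the 0.15 nitrogen
#' weight so both dimensions contribute comparably), all others receive only
#' baseline noise, and residues listed in `unassigned` carry `NA` shifts
#' (downstream reporting applies the conventional -0.1 ppm display
#' sentinel).
#'
#' @param n_residues Protein length; calmodulin has 148 residues.
#' @param perturbed_range Length-2 integer range (first, last residue) of the
#'   perturbed region; default the C-lobe (88-148).
#' @param shift_magnitude Scale of perturbed-region 1H shifts (ppm), >= 0.
#' @param unassigned Integer vector of unassigned residue indices.
#' @param noise_sd Baseline shift noise s.d. (ppm).
#' @param seed Integer RNG seed.
#' @return Tibble with `residue`, `dH_ppm`, `dN_ppm`, `assigned`.
#' @export
gen_csp_table <- function(n_residues = 148, perturbed_range = c(88, 148),
                          shift_magnitude = 0.1, unassigned = integer(),
                          noise_sd = 0.005, seed) {
  n_residues <- check_count(n_residues, "n_residues")
  if (length(perturbed_range) != 2L ||
      perturbed_range[1] < 1 || perturbed_range[2] > n_residues ||
      perturbed_range[1] > perturbed_range[2]) {
    abort("`perturbed_range` must lie within [1, n_residues].",
          class = "camiks_validation_error")
  }
  check_non_negative(shift_magnitude, "shift_magnitude")
  check_non_negative(noise_sd, "noise_sd")
  if (length(unassigned) && (any(unassigned < 1) ||
                             any(unassigned > n_residues))) {
    abort("`unassigned` indices must lie within [1, n_residues].",
          class = "camiks_validation_error")
  }
  check_seed(seed)

  residue <- seq_len(n_residues)
  perturbed <- residue >= perturbed_range[1] & residue <= perturbed_range[2]
  out <- with_seed(seed, {
    dh <- rnorm(n_residues, sd = noise_sd) +
      perturbed * rnorm(n_residues, sd = shift_magnitude)
    dn <- rnorm(n_residues, sd = noise_sd / 0.15) +
      perturbed * rnorm(n_residues, sd = shift_magnitude / 0.15)
    tibble(residue = residue, dH_ppm = dh, dN_ppm = dn,
           assigned = !(residue %in% unassigned))
  })
  out$dH_ppm[!out$assigned] <- NA_real_
  out$dN_ppm[!out$assigned] <- NA_real_
  attr(out, "params") <- list(n_residues = n_residues,
                              perturbed_range = perturbed_range,
                              shift_magnitude = shift_magnitude,
                              unassigned = unassigned,
                              noise_sd = noise_sd, seed = seed)
  out
}
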
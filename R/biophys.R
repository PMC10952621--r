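#' Combined amide chemical-shift perturbation
#'
#' \eqn{\Delta\delta = \sqrt{(\Delta H)^2 + (0.15\,\Delta N)^2}} in ppm,
#' the conventional 1H/15N weighting for HSQC peak displacements.
#' Sign-invariant and non-negative; `NA` in either dimension yields `NA`
#' (an unassigned residue).
#'
#' @param dH Proton shift difference(s), ppm.
#' @param dN Nitrogen shift difference(s), ppm.
#' @return Numeric vector of combined shifts (ppm).
#' @export
csp <- function(dH, dN) {
  if (length(dH) != length(dN)) {
    abort("`dH` and `dN` must have the same length.",
          class = "camiks_validation_error")
  }
  sqrt(dH^2 + (0.15 * dN)^2)
}

#' Per-residue CSP table with display sentinel
#'
#' Computes \eqn{\Delta\delta} for each residue of a peak table and, purely
#' for reporting/plotting, marks unassigned residues with the conventional
#' arbitrary value of -0.1 ppm.  The sentinel never enters numeric
#' aggregation: `delta` keeps `NA` for unassigned residues and only
#' `delta_display` carries -0.1.
#'
#' @param peaks Tibble with `residue`, `dH_ppm`, `dN_ppm` and optionally
#'   `assigned` (defaults to non-missing shifts).
#' @param sentinel Display value for unassigned residues (default -0.1 ppm).
#' @return Input tibble plus `delta` and `delta_display` columns.
#' @export
csp_table <- function(peaks, sentinel = -0.1) {
  peaks <- as_tibble(peaks)
  if (!all(c("residue", "dH_ppm", "dN_ppm") %in% names(peaks))) {
    abort("`peaks` must have columns `residue`, `dH_ppm`, `dN_ppm`.",
          class = "camiks_validation_error")
  }
  if (!"assigned" %in% names(peaks)) {
    peaks$assigned <- !(is.na(peaks$dH_ppm) | is.na(peaks$dN_ppm))
  }
  peaks |>
    mutate(
      delta = ifelse(.data$assigned, csp(.data$dH_ppm, .data$dN_ppm),
                     NA_real_),
      delta_display = ifelse(.data$assigned, .data$delta, sentinel)
    )
}

#' Flow-cytometry channel surface density
#'
#' Fraction of channel-expressing cells whose channels are detected at the
#' cell surface:
#' (double-positive cells - surface-label-only cells) / channel-positive
#' cells, clipped to \[0, 1\].  The three counts come from independent gates
#' on the same acquisition.
#'
#' @param ecfp_af647_pos Count of cells positive for both the channel
#'   fluorophore and the surface label.
#' @param af647_only_pos Count positive for the surface label only
#'   (background labelling).
#' @param ecfp_pos Count positive for the channel fluorophore; must be > 0.
#' @return Surface density fraction(s) in \[0, 1\].
#' @export
surface_density <- function(ecfp_af647_pos, af647_only_pos, ecfp_pos) {
  counts <- list(ecfp_af647_pos = ecfp_af647_pos,
                 af647_only_pos = af647_only_pos, ecfp_pos = ecfp_pos)
  for (nm in names(counts)) {
    if (any(!is.finite(counts[[nm]])) || any(counts[[nm]] < 0)) {
      abort(sprintf("`%s` must be finite and >= 0.", nm),
            class = "camiks_validation_error")
    }
  }
  if (any(ecfp_pos == 0)) {
    abort("`ecfp_pos` must be > 0 (no channel-positive cells gated).",
          class = "camiks_validation_error")
  }
  pmin(1, pmax(0, (ecfp_af647_pos - af647_only_pos) / ecfp_pos))
}

#' Fraction of intact protein from gel densitometry
#'
#' Normalises band intensities of a limited-proteolysis series by the
#' zero-protease reference lane, giving the fraction of intact protein per
#' protease concentration.
#'
#' @param lanes Tibble with `protease_conc` (mg/ml) and `band_intensity`
#'   (arbitrary units); must include a lane at protease concentration zero.
#' @return Input tibble plus `fraction_intact`, sorted by protease
#'   concentration.
#' @export
fraction_intact <- function(lanes) {
  lanes <- as_tibble(lanes)
  if (!all(c("protease_conc", "band_intensity") %in% names(lanes))) {
    abort("`lanes` must have columns `protease_conc` and `band_intensity`.",
          class = "camiks_validation_error")
  }
  ref <- lanes$band_intensity[lanes$protease_conc == 0]
  if (length(ref) == 0) {
    abort("a zero-protease reference lane is required.",
          class = "camiks_validation_error")
  }
  lanes |>
    arrange(.data$protease_conc) |>
    mutate(fraction_intact = .data$band_intensity / mean(ref))
}

#' Molar extinction coefficient at 280 nm from sequence composition
#'
#' \eqn{\epsilon_0 = 5500 \cdot \#Trp + 1490 \cdot \#Tyr + 125 \cdot
#' \#cystine} (M^-1 cm^-1), the standard composition-based estimate.
#' Reduced cysteines contribute nothing (the default); with
#' `oxidized = TRUE` every pair of cysteines is counted as one cystine.
#' Additive over concatenated sequences (when fully reduced).
#'
#' @param sequence Amino-acid sequence(s), standard one-letter codes.
#' @param oxidized Count cysteine pairs as disulfides? Default `FALSE`.
#' @return Extinction coefficient(s), M^-1 cm^-1.
#' @export
extinction_coefficient <- function(sequence, oxidized = FALSE) {
  vapply(sequence, function(s) {
    aa <- strsplit(toupper(gsub("\\s", "", s)), "")[[1]]
    bad <- setdiff(aa, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    if (length(bad)) {
      abort(paste0("unknown residue code(s): ",
                   paste(unique(bad), collapse = ", ")),
            class = "camiks_validation_error")
    }
    n_trp <- sum(aa == "W")
    n_tyr <- sum(aa == "Y")
    n_cystine <- if (oxidized) floor(sum(aa == "C") / 2) else 0
    5500 * n_trp + 1490 * n_tyr + 125 * n_cystine
  }, numeric(1), USE.NAMES = FALSE)
}

#' Kv7.1 calmodulin-binding peptides and the calmodulin sequence
#'
#' The two synthesised Kv7.1 C-terminal peptides used for binding work --
#' helix A (residues 370-389) and helix B (residues 507-536) -- and the
#' mature human calmodulin sequence (read from the FASTA fixture shipped
#' with the package).
#'
#' @return Named character vector with entries `HA`, `HB`, `CaM`.
#' @export
kv71_peptides <- function() {
  fasta <- system.file("extdata", "calmodulin_human.fasta",
                       package = "camiks", mustWork = TRUE)
  lines <- readLines(fasta)
  cam <- paste(lines[!startsWith(lines, ">")], collapse = "")
  c(
    HA = "AAASLIQTAWRCYAAENPDS",
    HB = "REHHRATIKVIRRMQYFVAKKKFQQARKPY",
    CaM = cam
  )
}
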
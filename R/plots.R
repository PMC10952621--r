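#' Plot an action-potential trace
#'
#' Membrane potential against time, one panel per recorded beat if several
#' are present.
#'
#' @param object An `ap_trace` tibble from [pace()].
#' @param ... Unused.
#' @export
autoplot.ap_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$v_mV)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$beat), labeller = "label_both") +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)")
}

#' Plot a binding-fit isotherm
#'
#' Measured per-injection heats (normalised per mole of injectant) against
#' molar ratio, with the fitted isotherm overlaid.
#'
#' @param object A `binding_fit`.
#' @param ... Unused.
#' @export
autoplot.binding_fit <- function(object, ...) {
  conc <- itc_concentrations(object$experiment)
  inj_moles <- object$experiment$syringe_conc *
    conc$volume_ul * 1e-6               # mol per injection
  df <- tibble(
    molar_ratio = conc$X_t / conc$M_t,
    measured = object$experiment$injections$heat_ucal / (inj_moles * 1e9),
    fitted = object$fitted / (inj_moles * 1e9)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$molar_ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$measured)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red3") +
    ggplot2::labs(x = "molar ratio", y = "kcal per mol of injectant")
}

#' Plot a melt fit
#' @param object A `melt_fit`.
#' @param ... Unused.
#' @export
autoplot.melt_fit <- function(object, ...) {
  df <- mutate(object$data, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(.data$temp_C)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$signal), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red3") +
    ggplot2::geom_vline(xintercept = object$t_m, linetype = 2) +
    ggplot2::labs(x = "temperature (°C)", y = "normalised signal")
}

#' Plot per-residue chemical-shift perturbations
#'
#' Bar plot of combined shifts with unassigned residues shown at the
#' display sentinel.
#'
#' @param tbl Output of [csp_table()].
#' @return A ggplot object.
#' @export
plot_csp <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(.data$residue, .data$delta_display,
                                    fill = .data$assigned)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey25",
                                          `FALSE` = "red3")) +
    ggplot2::labs(x = "residue", y = expression(Delta * delta ~ "(ppm)"))
}

#' Plot APD prolongation against block fraction
#'
#' The relative APD50 increase for each calibrated variant against its
#' fractional peak-IKs reduction.
#'
#' @param object An `apd_comparison` tibble.
#' @param ... Unused.
#' @export
autoplot.apd_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(100 * .data$target_r,
                                       .data$relative_increase)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$variant),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "peak IKs reduction (%)",
                  y = "APD50 increase vs WT (%)")
}
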
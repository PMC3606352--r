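#' Kinetic and physical parameters of the remodeling model
#'
#' Single source of truth for the model coefficients. Defaults are the
#' regression-derived values used throughout the package: the BrdU labeling
#' surface (amplitude `A`, time decay `B`, spatial decay `D`), the TUNEL
#' apoptosis surface (`E`, `F`, `H`), the monocyte entry rate (`J`, `K`),
#' the labeling-kinetics constants (`T_B`, `T_D`, `brdu_window`,
#' `cell_cycle`), and the physical constants (viscosity `mu`, reference
#' shear `tau_ref`, lattice pitch `element_size`).
#'
#' The static depth-profile amplitudes reported alongside these fits
#' (C = 23.8% for BrdU at the luminal surface, G = 19.3% for TUNEL at the
#' outer wall) are reference values only: the model recomputes the
#' time-dependent normalizers C*(t) and G*(t) at every step via
#' [spatial_normalizer()] so that depth-integrated probabilities match the
#' space-averaged ones.
#'
#' @param A BrdU labeling amplitude at t = 0, percent. Default 44.
#' @param B BrdU time-decay coefficient, per day. Default 0.16.
#' @param D BrdU spatial-decay coefficient, per mm (decay with distance from
#'   the lumen). Default 27.3.
#' @param E TUNEL labeling amplitude at t = 0, percent. Default 5.0.
#' @param F_ TUNEL time-decay coefficient, per day. Default 0.32. (Named
#'   `F_` to avoid masking `FALSE`; the coefficient is stored as `F`.)
#' @param H TUNEL spatial-decay coefficient, per mm (decay with distance
#'   from the outer wall). Default 6.7.
#' @param J Maximal monocyte entry rate at t = 0, monocytes per mm^2 per
#'   hour. Default 175.
#' @param K Monocyte entry-rate time decay, per day. Default 0.16.
#' @param T_B Interval from BrdU injection to tissue harvest, hours.
#'   Default 24.
#' @param T_D Residence time of apoptotic cells in the tissue, hours.
#'   Default 24.
#' @param brdu_window Metabolic availability of BrdU after injection,
#'   hours. Default 2.
#' @param cell_cycle SMC cell-cycle time, hours; G1, S and G2/M each occupy
#'   one third. Default 24.
#' @param mu Blood viscosity, poise. Default 0.035.
#' @param tau_ref Pre-ligation reference wall shear used to normalize
#'   shear (tau* = tau / tau_ref), dynes/cm^2. Default 10.
#' @param element_size Lattice pitch, micrometres; one element approximates
#'   one SMC. Default 7.
#' @param init_smc_fraction Fraction of the initial single layer assigned
#'   as SMC (the rest is ECM). Default 0.25.
#' @param monocyte_baseline_content Monocytes seeded at t = 0 as a fraction
#'   of the initial element count. Default 0.05.
#' @param shear_response Functional form of the shear factor S(tau*)
#'   multiplying the labeling amplitudes and the monocyte entry rate:
#'   `"exponential"` gives S = exp(-tau*), `"inverse"` gives S = 1/tau*.
#'
#' @return An object of class `vg_params`: a validated named list.
#' @examples
#' p <- vg_params()
#' brdu_fraction(tau_star = 1, t = 0, params = p)
#' @export
vg_params <- function(A = 44, B = 0.16, D = 27.3,
                      E = 5.0, F_ = 0.32, H = 6.7,
                      J = 175, K = 0.16,
                      T_B = 24, T_D = 24,
                      brdu_window = 2, cell_cycle = 24,
                      mu = 0.035, tau_ref = 10,
                      element_size = 7,
                      init_smc_fraction = 0.25,
                      monocyte_baseline_content = 0.05,
                      shear_response = c("exponential", "inverse")) {
  shear_response <- match.arg(shear_response)
  p <- list(
    A = A, B = B, D = D, E = E, F = F_, H = H, J = J, K = K,
    T_B = T_B, T_D = T_D, brdu_window = brdu_window,
    cell_cycle = cell_cycle, mu = mu, tau_ref = tau_ref,
    element_size = element_size,
    init_smc_fraction = init_smc_fraction,
    monocyte_baseline_content = monocyte_baseline_content,
    shear_response = shear_response
  )
  validate_vg_params(p)
  structure(p, class = "vg_params")
}

validate_vg_params <- function(p) {
  num <- c("A", "B", "D", "E", "F", "H", "J", "K", "T_B", "T_D",
           "brdu_window", "cell_cycle", "mu", "tau_ref", "element_size")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive finite number.", nm))
    }
  }
  if (p$init_smc_fraction <= 0 || p$init_smc_fraction >= 1) {
    abort("`init_smc_fraction` must lie strictly between 0 and 1.")
  }
  if (p$monocyte_baseline_content < 0 || p$monocyte_baseline_content >= 1) {
    abort("`monocyte_baseline_content` must lie in [0, 1).")
  }
  if (p$brdu_window > p$cell_cycle / 3) {
    abort("`brdu_window` must not exceed one cell-cycle phase (cell_cycle / 3).")
  }
  invisible(p)
}

as_vg_params <- function(x) {
  if (inherits(x, "vg_params")) return(x)
  if (is.list(x)) {
    names(x)[names(x) == "F"] <- "F_"  # `F` is stored; the constructor arg is `F_`
    return(do.call(vg_params, x))
  }
  abort("`params` must be a `vg_params` object or a named list.")
}

#' @export
print.vg_params <- function(x, ...) {
  cat("<vg_params>\n")
  cat(sprintf("  BrdU surface:   A = %g%%, B = %g/day, D = %g/mm\n", x$A, x$B, x$D))
  cat(sprintf("  TUNEL surface:  E = %g%%, F = %g/day, H = %g/mm\n", x$E, x$F, x$H))
  cat(sprintf("  Monocytes:      J = %g/(mm^2 h), K = %g/day\n", x$J, x$K))
  cat(sprintf("  Labeling:       T_B = %g h, T_D = %g h, window = %g h, cycle = %g h\n",
              x$T_B, x$T_D, x$brdu_window, x$cell_cycle))
  cat(sprintf("  Physical:       mu = %g poise, tau_ref = %g dyn/cm^2, element = %g um\n",
              x$mu, x$tau_ref, x$element_size))
  cat(sprintf("  Shear response: %s\n", x$shear_response))
  invisible(x)
}

#' Shear-response factor S(tau*)
#'
#' Dimensionless factor through which normalized wall shear modulates the
#' labeling amplitudes and the monocyte entry rate. Two presets are
#' supported: `"exponential"`, S(tau*) = exp(-tau*), and `"inverse"`,
#' S(tau*) = 1/tau*. Low shear yields a larger factor under both forms, so
#' proliferation, apoptosis labeling and monocyte entry are all enhanced in
#' low-flow grafts.
#'
#' @param tau_star Normalized wall shear (tau / tau_ref), positive.
#' @param params A [vg_params()] object (its `shear_response` selects the
#'   form), or a form name.
#' @return Numeric vector of factors.
#' @examples
#' shear_factor(c(0.18, 1, 1.4))
#' @export
shear_factor <- function(tau_star, params = vg_params()) {
  form <- if (is.character(params)) params else as_vg_params(params)$shear_response
  if (any(!is.finite(tau_star)) || any(tau_star <= 0)) {
    abort("`tau_star` must be positive and finite.")
  }
  switch(form,
    exponential = exp(-tau_star),
    inverse = 1 / tau_star,
    abort(sprintf("Unknown shear response form '%s'.", form))
  )
}
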
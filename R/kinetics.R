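#' Wall shear stress from Poiseuille's law
#'
#' Estimates wall shear stress for laminar tube flow, tau = 4 mu Q / (pi R^3).
#' With CGS inputs (Q in mL/s, R in cm, mu in poise) the result is in
#' dynes/cm^2.
#'
#' @param Q Volumetric flow rate, mL/s (non-negative).
#' @param R Lumen radius, cm (positive).
#' @param mu Viscosity, poise (positive). Default 0.035.
#' @return Wall shear stress, dynes/cm^2.
#' @examples
#' poiseuille_shear(Q = 0.5, R = 0.15)
#' @export
poiseuille_shear <- function(Q, R, mu = 0.035) {
  if (any(!is.finite(R)) || any(R <= 0)) abort("`R` must be positive.")
  if (any(!is.finite(mu)) || any(mu <= 0)) abort("`mu` must be positive.")
  if (any(!is.finite(Q)) || any(Q < 0)) abort("`Q` must be non-negative.")
  4 * mu * Q / (pi * R^3)
}

check_tau_t <- function(tau_star, t) {
  if (any(!is.finite(tau_star)) || any(tau_star <= 0)) {
    abort("`tau_star` must be positive.")
  }
  if (any(!is.finite(t)) || any(t < 0)) abort("`t` must be non-negative (days).")
}

#' Expected BrdU-positive fraction of intimal SMC nuclei
#'
#' Labeling surface for proliferation: `A * S(tau_star) * exp(-B t)`, the
#' expected percentage of BrdU-positive SMC nuclei as a function of
#' normalized wall shear and implantation time. Low shear and early time
#' give the highest labeling.
#'
#' @param tau_star Normalized wall shear (tau / tau_ref), positive.
#' @param t Implantation time, days.
#' @param params A [vg_params()] object.
#' @return Percent BrdU-positive nuclei.
#' @examples
#' brdu_fraction(tau_star = 0.18, t = c(0, 7, 14, 28))
#' @export
brdu_fraction <- function(tau_star, t, params = vg_params()) {
  params <- as_vg_params(params)
  check_tau_t(tau_star, t)
  params$A * shear_factor(tau_star, params) * exp(-params$B * t)
}

#' Expected TUNEL-positive fraction of intimal SMC
#'
#' Labeling surface for apoptosis: `E * S(tau_star) * exp(-F t)`, mirroring
#' [brdu_fraction()] with the TUNEL amplitude and time decay.
#'
#' @inheritParams brdu_fraction
#' @return Percent TUNEL-positive cells.
#' @export
tunel_fraction <- function(tau_star, t, params = vg_params()) {
  params <- as_vg_params(params)
  check_tau_t(tau_star, t)
  params$E * shear_factor(tau_star, params) * exp(-params$F * t)
}

# Pieces of the forward labeling model shared by the forward map and its
# inversion. A division at cycle-time T implies S-phase during
# [T - 2 Tc/3, T - Tc/3]; label is acquired iff that interval overlaps the
# availability window [0, w], i.e. T in [Tc/3, 2 Tc/3 + w]. Cells are
# asynchronous: a fraction phi = p * Tc is cycling with division times
# uniform on (0, Tc]; dividing labeled cells contribute two labeled nuclei,
# labeled cells still undivided at harvest contribute one.
labeling_geometry <- function(params, T_harvest) {
  Tc <- params$cell_cycle
  S_dur <- Tc / 3
  upper <- min(2 * S_dur + params$brdu_window, Tc)
  div_horizon <- min(T_harvest, Tc)
  lab_div <- max(0, min(upper, T_harvest) - S_dur)
  lab_undiv <- max(0, upper - max(T_harvest, S_dur))
  list(Tc = Tc, M = 2 * lab_div + lab_undiv, div_horizon = div_horizon)
}

#' Forward labeling model: expected labeled fraction at harvest
#'
#' Given a population in which divisions occur at per-hour probability
#' `p_hourly`, predicts the percentage of labeled nuclei at harvest under
#' the labeling-kinetics assumptions: label is metabolically available for
#' `brdu_window` hours after injection, incorporation occurs only in
#' S-phase, the cell cycle lasts `cell_cycle` hours with G1/S/G2M in equal
#' thirds, both daughters inherit the label, and tissue is harvested
#' `T_B` hours after injection. The population is asynchronous: a fraction
#' `p_hourly * cell_cycle` of cells is actively cycling, uniformly
#' distributed in cycle phase.
#'
#' This forward map is the normative definition from which
#' [mean_division_prob()] is the exact inverse.
#'
#' @param p_hourly Per-hour division probability, in `[0, 1)`.
#' @param T_B Injection-to-harvest interval in hours; defaults to the value
#'   in `params`.
#' @param params A [vg_params()] object.
#' @return Expected percent labeled nuclei at harvest.
#' @examples
#' label_fraction_forward(0.01)            # ~16% at defaults
#' label_fraction_forward(mean_division_prob(30))  # round-trips to 30
#' @export
label_fraction_forward <- function(p_hourly, T_B = NULL, params = vg_params()) {
  params <- as_vg_params(params)
  if (is.null(T_B)) T_B <- params$T_B
  if (any(!is.finite(p_hourly)) || any(p_hourly < 0) || any(p_hourly >= 1)) {
    abort("`p_hourly` must lie in [0, 1).")
  }
  g <- labeling_geometry(params, T_B)
  phi <- pmin(p_hourly * g$Tc, 1)
  100 * (phi / g$Tc * g$M) / (1 + phi * g$div_horizon / g$Tc)
}

invert_labeling <- function(pct, T_harvest, params, what) {
  if (any(!is.finite(pct)) || any(pct < 0) || any(pct >= 100)) {
    abort(sprintf("`%s` must lie in [0, 100).", what))
  }
  g <- labeling_geometry(params, T_harvest)
  b_max <- 100 * g$M / (g$Tc + g$div_horizon)
  over <- pct > b_max + 1e-12
  if (any(over)) {
    warn(sprintf(
      "%s of %.3g%% exceeds the %.3g%% ceiling of the labeling model (all cells cycling); probability clamped to 1/cell_cycle.",
      what, max(pct), b_max
    ))
  }
  bh <- pmin(pct, b_max) / 100
  p <- bh / (g$M - bh * g$div_horizon)
  pmin(p, 1 / g$Tc)
}

#' Space-averaged per-hour SMC division probability from a BrdU index
#'
#' Exact inverse of [label_fraction_forward()]: converts a measured
#' percentage of BrdU-positive nuclei into the per-hour space-averaged
#' probability of SMC division. At default constants the closed form is
#' `p = b / (2000 - 24 b)` with `b` in percent. Values above the labeling
#' model's ceiling (all cells cycling, about 41.7% at defaults) are clamped
#' with a warning.
#'
#' @param brdu_pct Percent BrdU-positive nuclei, in `[0, 100)`.
#' @param params A [vg_params()] object.
#' @return Per-hour division probability.
#' @examples
#' mean_division_prob(16.2)
#' @export
mean_division_prob <- function(brdu_pct, params = vg_params()) {
  params <- as_vg_params(params)
  invert_labeling(brdu_pct, params$T_B, params, "brdu_pct")
}

#' Space-averaged per-hour SMC apoptosis probability from a TUNEL index
#'
#' Applies the same labeling-kinetics correlation as
#' [mean_division_prob()], with the apoptotic-cell residence time `T_D`
#' taking the place of the injection-to-harvest interval.
#'
#' @param tunel_pct Percent TUNEL-positive cells, in `[0, 100)`.
#' @param params A [vg_params()] object.
#' @return Per-hour apoptosis probability.
#' @export
mean_apoptosis_prob <- function(tunel_pct, params = vg_params()) {
  params <- as_vg_params(params)
  invert_labeling(tunel_pct, params$T_D, params, "tunel_pct")
}

#' Depth-profile normalizer for exponential probability profiles
#'
#' Returns the amplitude `c` such that an exponential depth profile
#' `c * exp(-decay * x)` integrates over the intimal thickness to the
#' space-averaged probability: `int_0^IT c exp(-decay x) dx = mean_p * IT`.
#' Closed form `c = mean_p * IT * decay / (1 - exp(-decay * IT))`; as
#' `decay * IT -> 0` this tends to `mean_p` (uniform profile).
#'
#' @param mean_p Space-averaged per-hour probability.
#' @param IT Intimal thickness, mm (positive).
#' @param decay Spatial decay coefficient, per mm (positive).
#' @return The profile amplitude (probability per hour at x = 0).
#' @examples
#' spatial_normalizer(0.01, IT = 0.1, decay = 27.3)
#' @export
spatial_normalizer <- function(mean_p, IT, decay) {
  if (any(!is.finite(IT)) || any(IT <= 0)) abort("`IT` must be positive (mm).")
  if (any(!is.finite(decay)) || any(decay <= 0)) abort("`decay` must be positive (per mm).")
  z <- decay * IT
  # series for small z avoids 0/0; expm1 keeps precision elsewhere
  ifelse(z < 1e-8, mean_p * (1 + z / 2), mean_p * z / (-expm1(-z)))
}

clip_probability <- function(p, label) {
  if (any(p > 1)) {
    warn(sprintf("%s exceeded 1 and was clipped; parameters may be pathological.", label))
  }
  pmin(pmax(p, 0), 1)
}

#' Per-hour SMC division probability at a depth below the lumen
#'
#' The full division-probability surface: `C*(t) exp(-D d_lumen)` where
#' `C*(t)` is the depth normalizer of the space-averaged division
#' probability at `(tau_star, t)` over the local intimal thickness.
#' Division is concentrated in the most superficial (luminal) portion of
#' the intima; the element-weighted depth average recovers the
#' space-averaged probability.
#'
#' @inheritParams brdu_fraction
#' @param d_lumen Distance from the luminal surface, mm, in `[0, IT]`.
#' @param IT Local intimal thickness, mm (positive).
#' @return Per-hour division probability, clipped to `[0, 1]`.
#' @examples
#' division_prob_at(1, t = 3, d_lumen = c(0.0035, 0.05), IT = 0.07)
#' @export
division_prob_at <- function(tau_star, t, d_lumen, IT, params = vg_params()) {
  params <- as_vg_params(params)
  if (any(d_lumen < 0) || any(d_lumen > IT + 1e-12)) {
    abort("`d_lumen` must lie in [0, IT].")
  }
  mean_p <- mean_division_prob(brdu_fraction(tau_star, t, params), params)
  cstar <- spatial_normalizer(mean_p, IT, params$D)
  clip_probability(cstar * exp(-params$D * d_lumen), "division probability")
}

#' Per-hour SMC apoptosis probability at a depth above the outer wall
#'
#' The apoptosis surface `G*(t) exp(-H d_outer)`, with `G*(t)` the depth
#' normalizer of the space-averaged apoptosis probability. Apoptosis is
#' concentrated in the outermost portion of the intima (largest near the
#' outer wall, `d_outer = 0`).
#'
#' @inheritParams brdu_fraction
#' @param d_outer Distance from the outer boundary of the intima, mm, in
#'   `[0, IT]`.
#' @param IT Local intimal thickness, mm (positive).
#' @return Per-hour apoptosis probability, clipped to `[0, 1]`.
#' @export
apoptosis_prob_at <- function(tau_star, t, d_outer, IT, params = vg_params()) {
  params <- as_vg_params(params)
  if (any(d_outer < 0) || any(d_outer > IT + 1e-12)) {
    abort("`d_outer` must lie in [0, IT].")
  }
  mean_p <- mean_apoptosis_prob(tunel_fraction(tau_star, t, params), params)
  gstar <- spatial_normalizer(mean_p, IT, params$H)
  clip_probability(gstar * exp(-params$H * d_outer), "apoptosis probability")
}

#' Net monocyte entry rate into the intima
#'
#' `J * S(tau_star) * exp(-K t)`: an early, shear-dependent burst of
#' monocyte entry that tapers toward baseline, sharing the time/shear form
#' of the proliferation surface.
#'
#' @inheritParams brdu_fraction
#' @return Entry rate, monocytes per mm^2 per hour.
#' @examples
#' monocyte_influx(tau_star = 0.18, t = c(0, 7, 14))
#' @export
monocyte_influx <- function(tau_star, t, params = vg_params()) {
  params <- as_vg_params(params)
  check_tau_t(tau_star, t)
  params$J * shear_factor(tau_star, params) * exp(-params$K * t)
}

#' Normalized monocyte entry rate
#'
#' The dimensionless drive of matrix augmentation: the entry rate at
#' `(tau_star, t)` divided by the rate at the normal condition, which is
#' the maximal entry rate `J` (unit shear factor) at time zero — the rate
#' that maintains the baseline monocyte content of the wall. With
#' `normalization = "baseline"` (default) the drive is
#' `S(tau_star) exp(-K t)` and decays in time; `"same_time"` divides by
#' the reference rate at the same time, cancelling the decay. A drive of
#' 1 corresponds to two burst ECM elements per daughter cell
#' ([matrix_burst_count()]).
#'
#' @inheritParams brdu_fraction
#' @param normalization `"baseline"` or `"same_time"`.
#' @return Dimensionless normalized entry rate.
#' @export
monocyte_norm <- function(tau_star, t, params = vg_params(),
                          normalization = c("baseline", "same_time")) {
  params <- as_vg_params(params)
  normalization <- match.arg(normalization)
  decay <- if (normalization == "baseline") exp(-params$K * t) else rep_len(1, length(t))
  shear_factor(tau_star, params) * decay
}

#' Matrix elements produced per daughter cell at division
#'
#' Monocyte-augmented matrix burst: each of the two daughter cells deposits
#' `[2 * m_norm]` ECM elements at the time of division, where `m_norm` is
#' the normalized monocyte entry rate and `[ ]` rounds to the nearest
#' integer (half-values round up).
#'
#' @param m_norm Normalized monocyte entry rate, non-negative.
#' @return Integer count of ECM elements per daughter cell.
#' @examples
#' matrix_burst_count(c(0, 0.6, 1, 1.3))
#' @export
matrix_burst_count <- function(m_norm) {
  if (any(!is.finite(m_norm)) || any(m_norm < 0)) {
    abort("`m_norm` must be non-negative.")
  }
  as.integer(floor(2 * m_norm + 0.5))
}
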
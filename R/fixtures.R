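#' Parametric shear field for a focal stenosis
#'
#' Builds a smooth, strictly positive wall-shear field emulating the
#' hemodynamics of a focal lumen narrowing: shear is elevated at the
#' throat (flow conservation through the reduced cross-section; the throat
#' factor is `(1 - area_reduction)^(-3/2)`, the Poiseuille scaling of shear
#' with lumen area), depressed in the distal recirculation zone, and
#' relaxes toward baseline over time. The functional form (Gaussian throat
#' and distal dip) is a deliberately simple stand-in for a CFD-computed
#' field, which is outside the scope of this package.
#'
#' @param graft_length Graft length, mm. Default 20.
#' @param baseline_tau Baseline wall shear away from the stenosis,
#'   dynes/cm^2. Default 10.
#' @param throat_position Longitudinal position of the throat, mm.
#'   Default 10.
#' @param throat_width Gaussian width of the throat elevation, mm.
#'   Default 1.
#' @param area_reduction Fractional lumen cross-sectional area reduction
#'   at the throat, in (0, 1). Default 0.80.
#' @param distal_recovery_length Length over which the distal
#'   low-shear zone recovers, mm. Default 4.
#' @param time_decay Relaxation of the disturbance toward baseline, per
#'   day. Default 0.05.
#' @param times Days at which to tabulate the field.
#'   Default `c(0, 7, 14, 21, 28)`.
#' @param n_positions Longitudinal sampling points. Default 201.
#' @return A tibble (`position_mm`, `time_days`, `tau`), class
#'   `vg_shear_field`.
#' @examples
#' field <- generate_stenosis_field()
#' dplyr::summarise(dplyr::group_by(field, time_days),
#'                  min = min(tau), max = max(tau))
#' @export
generate_stenosis_field <- function(graft_length = 20, baseline_tau = 10,
                                    throat_position = 10, throat_width = 1,
                                    area_reduction = 0.80,
                                    distal_recovery_length = 4,
                                    time_decay = 0.05,
                                    times = c(0, 7, 14, 21, 28),
                                    n_positions = 201) {
  if (area_reduction < 0 || area_reduction >= 1) {
    abort("`area_reduction` must lie in [0, 1).")
  }
  if (graft_length <= 0 || throat_width <= 0 || distal_recovery_length <= 0) {
    abort("Lengths must be positive.")
  }
  x <- seq(0, graft_length, length.out = n_positions)
  throat_gain <- (1 - area_reduction)^(-3 / 2) - 1
  elev <- throat_gain * exp(-((x - throat_position) / throat_width)^2)
  dip_center <- throat_position + throat_width + distal_recovery_length / 2
  dip <- area_reduction *
    exp(-((x - dip_center) / (distal_recovery_length / 2))^2)
  df <- tidyr::expand_grid(time_days = times, position_mm = x)
  disturbance <- rep(elev - dip, times = length(times))  # position varies fastest
  df$tau <- baseline_tau * (1 + disturbance * exp(-time_decay * df$time_days))
  structure(df[, c("position_mm", "time_days", "tau")],
            class = c("vg_shear_field", "tbl_df", "tbl", "data.frame"))
}

#' Synthetic labeling dataset with known coefficients
#'
#' Samples the labeling surface `amp * S(tau_star) * exp(-decay * t)` at a
#' factorial design of shear levels and time points, optionally corrupted
#' by mean-one multiplicative log-normal noise; the test harness for
#' [fit_labeling_surface()].
#'
#' @param amp True amplitude, percent. Default 44.
#' @param decay True time-decay coefficient, per day. Default 0.16.
#' @param tau_star Shear levels of the design. Default `c(0.18, 1.4)`
#'   (the low- and high-flow graft sides).
#' @param t_days Time points, days. Default `c(1, 3, 7, 14, 28)`.
#' @param replicates Replicates per design point. Default 3.
#' @param sigma SD of the log multiplicative noise (0 = noise-free).
#' @param params A [vg_params()] (for the shear-response form).
#' @param seed Optional integer seed.
#' @return A tibble (`tau_star`, `t_days`, `percent_positive`).
#' @examples
#' generate_labeling_dataset(sigma = 0, replicates = 1)
#' @export
generate_labeling_dataset <- function(amp = 44, decay = 0.16,
                                      tau_star = c(0.18, 1.4),
                                      t_days = c(1, 3, 7, 14, 28),
                                      replicates = 3, sigma = 0,
                                      params = vg_params(), seed = NULL) {
  if (amp <= 0 || decay < 0) abort("`amp` must be positive and `decay` >= 0.")
  if (length(t_days) < 2) abort("Need at least two time points.")
  if (!is.null(seed)) set.seed(seed)
  params <- as_vg_params(params)
  design <- tidyr::expand_grid(tau_star = tau_star, t_days = t_days,
                               rep = seq_len(replicates))
  mu <- amp * shear_factor(design$tau_star, params) * exp(-decay * design$t_days)
  noise <- if (sigma > 0) {
    exp(rnorm(nrow(design), -sigma^2 / 2, sigma))  # mean-one multiplicative
  } else 1
  dplyr::select(
    dplyr::mutate(design, percent_positive = mu * noise),
    "tau_star", "t_days", "percent_positive")
}

#' Read and write shear-field tables
#'
#' CSV with header `position_mm,time_days,tau`; decimal point, comma
#' separator. Round-trips exactly.
#'
#' @param field A shear-field tibble.
#' @param path File path.
#' @return `write_shear_field()` returns `path` invisibly;
#'   `read_shear_field()` returns the validated tibble.
#' @export
write_shear_field <- function(field, path) {
  readr::write_csv(full_precision(validate_shear_field(field)), path)
  invisible(path)
}

# format doubles so that reading the CSV reproduces them bit-exactly
full_precision <- function(df) {
  df[] <- lapply(df, function(x) if (is.double(x)) sprintf("%.17g", x) else x)
  df
}

#' @rdname write_shear_field
#' @export
read_shear_field <- function(path) {
  # base read.csv: strtod parsing is correctly rounded, so full-precision
  # payloads round-trip bit-exactly
  df <- utils::read.csv(path, colClasses = "numeric")
  validate_shear_field(tibble::as_tibble(df))
}

#' Read and write labeling-data tables
#'
#' CSV with header `tau_star,t_days,percent_positive`; decimal point,
#' comma separator.
#'
#' @param data A labeling tibble (`tau_star`, `t_days`,
#'   `percent_positive`).
#' @param path File path.
#' @return `write_labeling_data()` returns `path` invisibly;
#'   `read_labeling_data()` returns the tibble.
#' @export
write_labeling_data <- function(data, path) {
  need <- c("tau_star", "t_days", "percent_positive")
  if (!all(need %in% names(data))) {
    abort("`data` needs columns tau_star, t_days, percent_positive.")
  }
  readr::write_csv(full_precision(data[, need]), path)
  invisible(path)
}

#' @rdname write_labeling_data
#' @export
read_labeling_data <- function(path) {
  tibble::as_tibble(utils::read.csv(path, colClasses = "numeric"))
}
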
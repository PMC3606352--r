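#' Simulation configuration
#'
#' Collects everything a run needs: duration and time step, domain mode and
#' size, the hemodynamic input (a constant wall shear or a
#' `(position, time, tau)` shear field), the monocyte module switches, and
#' the kinetic parameters.
#'
#' Exactly one of `tau` (constant shear, dynes/cm^2) or `shear_field` (a
#' data frame with columns `position_mm`, `time_days`, `tau`) must be
#' supplied. Shear from a field is refreshed every
#' `shear_update_interval` days with nearest-neighbor lookup in position
#' and time; constant-shear runs keep their shear fixed for the whole run.
#'
#' @param duration Simulated time, days (>= 0). Default 28.
#' @param dt Time step, hours; must divide 24. Default 1.
#' @param n_columns Longitudinal columns of the 2-D domain (ignored in 1-D,
#'   which always has one column). Default 100.
#' @param mode `"2d"` (mixed SMC/ECM initial layer) or `"1d"` (single
#'   column, single initial SMC).
#' @param tau Constant wall shear stress, dynes/cm^2.
#' @param shear_field Shear-field table (`position_mm`, `time_days`,
#'   `tau`), e.g. from [generate_stenosis_field()].
#' @param shear_update_interval Days between shear-field refreshes.
#'   Default 7.
#' @param monocyte_module Enable monocyte seeding, influx and the
#'   matrix-production burst at division. Default `TRUE`.
#' @param monocyte_normalization `"baseline"` (entry rate normalized to
#'   normal shear at time zero, so the burst decays with time) or
#'   `"same_time"` (normalized to normal shear at the same time).
#' @param macrophage_rule `"burst"` (each daughter deposits `[2 m_norm]`
#'   ECM at division) or `"plus_one"` (each daughter deposits exactly one
#'   additional ECM).
#' @param influx_coupling What the per-mm^2 monocyte entry rate multiplies:
#'   `"surface"` (default) treats it as a flux across each column's luminal
#'   surface patch, which keeps the monocyte content near its few-percent
#'   physiologic level; `"area"` multiplies by the growing intimal
#'   cross-section, making entry compound with wall thickness.
#' @param equivalent_columns Column count by which the 1-D intimal
#'   thickness is multiplied to report an equivalent 2-D intimal area.
#'   Default 100.
#' @param record_profile_days Days at which per-column heights are
#'   snapshotted (for stenosis profiles). Default `c(1, 7, 14, 28)`.
#' @param override_division_prob,override_apoptosis_prob Optional per-step
#'   probability overrides (recycled to the number of steps); `NA` entries
#'   leave the model probability in force. Intended for controlled
#'   experiments and tests.
#' @param params A [vg_params()] object.
#' @return A `sim_config` object.
#' @examples
#' cfg <- sim_config(duration = 7, mode = "1d", tau = 10)
#' @export
sim_config <- function(duration = 28, dt = 1,
                       n_columns = 100,
                       mode = c("2d", "1d"),
                       tau = NULL, shear_field = NULL,
                       shear_update_interval = 7,
                       monocyte_module = TRUE,
                       monocyte_normalization = c("baseline", "same_time"),
                       macrophage_rule = c("burst", "plus_one"),
                       influx_coupling = c("surface", "area"),
                       equivalent_columns = 100,
                       record_profile_days = c(1, 7, 14, 28),
                       override_division_prob = NULL,
                       override_apoptosis_prob = NULL,
                       params = vg_params()) {
  mode <- match.arg(mode)
  monocyte_normalization <- match.arg(monocyte_normalization)
  macrophage_rule <- match.arg(macrophage_rule)
  influx_coupling <- match.arg(influx_coupling)
  params <- as_vg_params(params)
  if (duration < 0) abort("`duration` must be >= 0 (days).")
  if (dt <= 0 || abs(24 / dt - round(24 / dt)) > 1e-9) {
    abort("`dt` must be a positive divisor of 24 hours.")
  }
  if (mode == "1d") n_columns <- 1L
  if (n_columns < 1) abort("`n_columns` must be >= 1.")
  if (is.null(tau) && is.null(shear_field)) {
    abort("Supply either a constant `tau` or a `shear_field`.")
  }
  if (!is.null(tau) && !is.null(shear_field)) {
    abort("Supply only one of `tau` and `shear_field`.")
  }
  if (!is.null(tau) && (!is.finite(tau) || tau <= 0)) {
    abort("`tau` must be positive (dynes/cm^2).")
  }
  if (!is.null(shear_field)) {
    shear_field <- validate_shear_field(shear_field)
  }
  structure(
    list(duration = duration, dt = dt, n_columns = as.integer(n_columns),
         mode = mode, tau = tau, shear_field = shear_field,
         shear_update_interval = shear_update_interval,
         monocyte_module = isTRUE(monocyte_module),
         monocyte_normalization = monocyte_normalization,
         macrophage_rule = macrophage_rule,
         influx_coupling = influx_coupling,
         equivalent_columns = as.integer(equivalent_columns),
         record_profile_days = record_profile_days,
         override_division_prob = override_division_prob,
         override_apoptosis_prob = override_apoptosis_prob,
         params = params),
    class = "sim_config"
  )
}

validate_shear_field <- function(field) {
  field <- tibble::as_tibble(field)
  need <- c("position_mm", "time_days", "tau")
  if (!all(need %in% names(field))) {
    abort("`shear_field` needs columns position_mm, time_days, tau.")
  }
  if (any(!is.finite(field$tau)) || any(field$tau <= 0)) {
    abort("`shear_field` must have tau > 0 everywhere.")
  }
  field
}

#' @export
print.sim_config <- function(x, ...) {
  shear <- if (!is.null(x$tau)) {
    sprintf("constant tau = %g dyn/cm^2", x$tau)
  } else {
    sprintf("shear field (%d rows, refresh every %g d)",
            nrow(x$shear_field), x$shear_update_interval)
  }
  cat(sprintf("<sim_config> %s, %d column(s), %g days @ dt = %g h\n",
              x$mode, x$n_columns, x$duration, x$dt))
  cat(sprintf("  %s; monocyte module %s (%s, %s rule)\n", shear,
              if (x$monocyte_module) "on" else "off",
              x$monocyte_normalization, x$macrophage_rule))
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Top-level keys map to [sim_config()] arguments; a `params` block maps to
#' [vg_params()] arguments. A `shear_field` key holding a CSV path loads
#' the field via [read_shear_field()].
#'
#' @param path YAML file path.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$params)) y$params <- do.call(vg_params, y$params)
  if (!is.null(y$shear_field) && is.character(y$shear_field)) {
    y$shear_field <- read_shear_field(y$shear_field)
  }
  do.call(sim_config, y)
}
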
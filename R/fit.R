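#' Calibrate labeling-surface coefficients from data
#'
#' Least-squares fit of the exponential labeling surface
#' `percent = amp * S(tau_star) * exp(-decay * t)` to a table of labeling
#' measurements, recovering the amplitude (percent at t = 0 under unit
#' shear factor) and the time-decay coefficient (per day). The shear
#' factor `S` is held at the configured form; starting values come from
#' the log-linear regression and are refined by [stats::nls()] in the
#' original scale (so the estimator is ordinary least squares on the
#' percentages, not on their logs).
#'
#' @param data Data frame with columns `tau_star`, `t_days`,
#'   `percent_positive` (>= 4 rows, non-degenerate in `t_days`).
#' @param params A [vg_params()]; selects the shear-response form.
#' @return A `labeling_fit` object; see [tidy.labeling_fit()] and
#'   [glance.labeling_fit()].
#' @examples
#' d <- generate_labeling_dataset(amp = 44, decay = 0.16, sigma = 0)
#' coef(fit_labeling_surface(d))
#' @export
fit_labeling_surface <- function(data, params = vg_params()) {
  params <- as_vg_params(params)
  need <- c("tau_star", "t_days", "percent_positive")
  if (!all(need %in% names(data))) {
    abort("`data` needs columns tau_star, t_days, percent_positive.")
  }
  data <- tibble::as_tibble(data)[, need]
  if (nrow(data) < 4) abort("Need at least 4 rows to fit the surface.")
  if (stats::var(data$t_days) == 0) {
    abort("Degenerate design: `t_days` takes a single value.")
  }
  if (any(data$percent_positive <= 0)) {
    abort("`percent_positive` must be positive for the labeling surface fit.")
  }
  s <- shear_factor(data$tau_star, params)
  # log-linear start: log(y) - log(S) = log(amp) - decay * t
  start_lm <- lm(log(percent_positive) - log(s) ~ t_days, data = data)
  start <- list(log_amp = unname(coef(start_lm)[1]),
                decay = -unname(coef(start_lm)[2]))
  start_fitted <- exp(start$log_amp) * s * exp(-start$decay * data$t_days)
  exact_start <- max(abs(data$percent_positive - start_fitted)) <
    1e-10 * max(data$percent_positive)
  # nls cannot iterate on zero-residual data; the log-linear start is then
  # already the least-squares solution
  fit <- if (exact_start) NULL else tryCatch(
    nls(percent_positive ~ exp(log_amp) * s * exp(-decay * t_days),
        data = cbind(data, s = s), start = start,
        control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    est <- c(amp = exp(start$log_amp), decay = start$decay)
    fitted_v <- est["amp"] * s * exp(-est["decay"] * data$t_days)
    se <- c(amp = NA_real_, decay = NA_real_)
  } else {
    cf <- coef(fit)
    est <- c(amp = unname(exp(cf["log_amp"])), decay = unname(cf["decay"]))
    sm <- summary(fit)$coefficients
    # delta method for amp = exp(log_amp)
    se <- c(amp = unname(exp(cf["log_amp"]) * sm["log_amp", "Std. Error"]),
            decay = unname(sm["decay", "Std. Error"]))
    fitted_v <- as.numeric(fitted(fit))
  }
  res <- data$percent_positive - fitted_v
  ss_tot <- sum((data$percent_positive - mean(data$percent_positive))^2)
  structure(
    list(coefficients = est, std_error = se,
         data = dplyr::mutate(data, fitted = fitted_v, residual = res),
         r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
         sigma = sqrt(sum(res^2) / max(nrow(data) - 2, 1)),
         n = nrow(data), shear_response = params$shear_response,
         nls = fit),
    class = "labeling_fit"
  )
}

#' @export
coef.labeling_fit <- function(object, ...) object$coefficients

#' @export
print.labeling_fit <- function(x, ...) {
  cat(sprintf(
    "<labeling_fit> amp = %.4g%%, decay = %.4g/day (n = %d, R^2 = %.3f, sigma = %.3g)\n",
    x$coefficients["amp"], x$coefficients["decay"], x$n, x$r_squared, x$sigma))
  invisible(x)
}

#' Tidy a labeling-surface fit
#'
#' @param x A `labeling_fit`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std.error`.
#' @export
tidy.labeling_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$std_error))
}

#' One-row summary of a labeling-surface fit
#'
#' @param x A `labeling_fit`.
#' @param ... Unused.
#' @return A tibble with `r.squared`, `sigma`, `nobs`.
#' @export
glance.labeling_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sigma = x$sigma, nobs = x$n)
}
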
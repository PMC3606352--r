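#' Plot a simulation trajectory
#'
#' Intimal area versus time, with element composition in a second panel.
#'
#' @param object A `vg_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vg_sim <- function(object, ...) {
  tr <- object$trajectory |>
    dplyr::select("time_days", "area_mm2", "smc_fraction",
                  "ecm_fraction", "monocyte_fraction") |>
    tidyr::pivot_longer(-"time_days", names_to = "metric")
  ggplot2::ggplot(tr, ggplot2::aes(.data$time_days, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Time (days)", y = NULL,
                  title = "Simulated intimal growth")
}

#' Plot ensemble growth curves
#'
#' Ensemble mean with a +/- 1 SD ribbon for the requested metric.
#'
#' @param object A `vg_ensemble`.
#' @param metric Trajectory metric to display. Default `"area_mm2"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vg_ensemble <- function(object, metric = "area_mm2", ...) {
  s <- dplyr::filter(object$summary, .data$metric == !!metric)
  ggplot2::ggplot(s, ggplot2::aes(.data$time_days, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (days)", y = metric,
                  title = sprintf("Ensemble of %d runs", object$n_runs))
}

#' Plot a grid snapshot
#'
#' Tile map of the lattice: columns along the graft, rows from the outer
#' boundary (bottom) to the lumen (top), colored by element kind.
#'
#' @param object A `vg_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vg_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$column, .data$row,
                                   fill = .data$kind)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(SMC = "#31a354", ECM = "grey70",
                                          MONOCYTE = "#de2d26")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Column (longitudinal)", y = "Row (outer -> lumen)",
                  fill = NULL)
}

#' Plot a shear field
#'
#' Shear stress along the graft, one line per tabulated time.
#'
#' @param object A `vg_shear_field` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vg_shear_field <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$position_mm, .data$tau,
                                       color = factor(.data$time_days))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Position (mm)", y = "Wall shear (dynes/cm^2)",
                  color = "Day")
}

#' Plot stenosis intimal-thickness profiles
#'
#' Per-column intimal thickness along the graft at the recorded days of a
#' [stenosis_run()].
#'
#' @param sim A `vg_sim` from [stenosis_run()].
#' @return A ggplot.
#' @export
plot_it_profile <- function(sim) {
  if (is.null(sim$it_profile)) abort("`sim` has no `it_profile`; use stenosis_run().")
  ggplot2::ggplot(sim$it_profile,
                  ggplot2::aes(.data$position_mm, .data$it_um,
                               color = factor(.data$day))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Position (mm)", y = "Intimal thickness (um)",
                  color = "Day")
}
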
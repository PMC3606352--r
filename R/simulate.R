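traj_metrics <- c("time_h", "n_smc", "n_ecm", "n_monocyte", "n_total",
                  "mean_height", "cum_divisions", "cum_apoptoses",
                  "cum_influx", "cum_ecm_scheduled", "cum_ecm_burst",
                  "cum_ecm_degraded", "cum_insertions", "cum_removals")

# tau* lookup matrix: one row per shear-update block, one column per lattice
# column. Constant shear collapses to a single row.
tau_star_matrix <- function(config) {
  p <- config$params
  if (!is.null(config$tau)) {
    return(matrix(config$tau / p$tau_ref, nrow = 1, ncol = config$n_columns))
  }
  field <- config$shear_field
  update_times <- seq(0, max(config$duration - 1e-9, 0),
                      by = config$shear_update_interval)
  if (config$duration > 0 &&
      max(field$time_days) + config$shear_update_interval < config$duration) {
    abort(sprintf(
      "`shear_field` does not cover the simulated span: times reach day %g but the run lasts %g days.",
      max(field$time_days), config$duration))
  }
  pos_range <- range(field$position_mm)
  col_pos <- if (config$n_columns == 1L) mean(pos_range) else {
    seq(pos_range[1], pos_range[2], length.out = config$n_columns)
  }
  ftimes <- sort(unique(field$time_days))
  mat <- matrix(NA_real_, nrow = length(update_times), ncol = config$n_columns)
  for (i in seq_along(update_times)) {
    ft <- ftimes[which.min(abs(ftimes - update_times[i]))]
    slice <- field[field$time_days == ft, ]
    idx <- vapply(col_pos, function(x) which.min(abs(slice$position_mm - x)),
                  integer(1))
    mat[i, ] <- slice$tau[idx] / p$tau_ref
  }
  mat
}

grid_to_cpp <- function(grid) {
  list(kind = grid$kind,
       last_div = grid$last_div,
       ecm_n = lapply(grid$ecm_n, function(x) {
         x <- as.integer(x); x[is.na(x)] <- 0L; x
       }))
}

grid_from_cpp <- function(fin, element_size) {
  new_vg_grid(lapply(fin$kind, as.integer), fin$last_div, fin$ecm_n,
              element_size, next_id = sum(lengths(fin$kind)) + 1L)
}

default_initial_grid <- function(config) {
  p <- config$params
  if (config$mode == "1d") {
    grid <- init_grid(1, mode = "single_smc_1d", element_size = p$element_size)
  } else {
    grid <- init_grid(config$n_columns, mode = "mixed_layer_2d",
                      init_smc_fraction = p$init_smc_fraction,
                      element_size = p$element_size)
  }
  if (config$monocyte_module) {
    n_mono <- round(p$monocyte_baseline_content * n_elements(grid))
    for (i in seq_len(n_mono)) {
      cc <- sample.int(length(grid$kind), 1)
      rr <- sample.int(length(grid$kind[[cc]]) + 1L, 1)
      grid <- insert_element(grid, cc, rr, vg_element("MONOCYTE"))
    }
  }
  grid
}

override_vec <- function(x, n_steps) {
  if (is.null(x)) return(numeric(0))
  v <- rep_len(as.numeric(x), n_steps)
  v[is.na(v)] <- -1
  v
}

run_core <- function(config, initial_grid, start_h = 0) {
  p <- config$params
  n_steps <- as.integer(round(config$duration * 24 / config$dt))
  prof_days <- config$record_profile_days
  prof_days <- sort(unique(prof_days[prof_days >= 0 & prof_days <= config$duration]))
  record_at <- as.integer(round(prof_days * 24 / config$dt))
  cfg <- list(
    n_steps = n_steps, dt_h = config$dt, start_h = start_h,
    mode1d = config$mode == "1d",
    monocyte_on = config$monocyte_module,
    mono_norm_baseline = config$monocyte_normalization == "baseline",
    macro_plus_one = config$macrophage_rule == "plus_one",
    influx_surface = config$influx_coupling == "surface",
    tau_star_mat = tau_star_matrix(config),
    update_steps = max(1L, as.integer(round(
      config$shear_update_interval * 24 / config$dt))),
    override_div = override_vec(config$override_division_prob, n_steps),
    override_apop = override_vec(config$override_apoptosis_prob, n_steps),
    record_heights_at = record_at,
    init = grid_to_cpp(initial_grid),
    params = unclass(p)
  )
  out <- cpp_run(cfg)
  list(out = out, profile_days = prof_days)
}

traj_tibble <- function(mat, config) {
  colnames(mat) <- traj_metrics
  df <- tibble::as_tibble(mat)
  p <- config$params
  es_mm <- p$element_size / 1000
  area <- if (config$mode == "1d") {
    df$mean_height * es_mm * config$equivalent_columns * es_mm
  } else {
    df$n_total * es_mm^2
  }
  dplyr::transmute(df,
    time_days = .data$time_h / 24,
    n_smc = .data$n_smc, n_ecm = .data$n_ecm,
    n_monocyte = .data$n_monocyte, n_total = .data$n_total,
    mean_it_um = .data$mean_height * p$element_size,
    area_mm2 = area,
    smc_fraction = ifelse(.data$n_total > 0, .data$n_smc / .data$n_total, NA_real_),
    ecm_fraction = ifelse(.data$n_total > 0, .data$n_ecm / .data$n_total, NA_real_),
    monocyte_fraction = ifelse(.data$n_total > 0,
                               .data$n_monocyte / .data$n_total, NA_real_),
    cum_divisions = .data$cum_divisions,
    cum_apoptoses = .data$cum_apoptoses,
    cum_influx = .data$cum_influx,
    cum_ecm_scheduled = .data$cum_ecm_scheduled,
    cum_ecm_burst = .data$cum_ecm_burst,
    cum_ecm_degraded = .data$cum_ecm_degraded,
    cum_insertions = .data$cum_insertions,
    cum_removals = .data$cum_removals)
}

#' Run one simulation
#'
#' Executes the hourly event loop from time zero to `duration`: per-column
#' shear and thickness lookup, SMC division draws (with lumen-ward
#' insertion of the new daughter and the monocyte-dependent matrix burst),
#' scheduled 24/48-hour matrix production, apoptosis draws (with removal of
#' the four nearest ECM elements), Poisson monocyte influx, and - in 2-D -
#' redistribution between adjacent columns. The run is fully deterministic
#' given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param initial_grid Optional starting [init_grid()] grid; by default the
#'   mode's standard initial configuration is built (with baseline
#'   monocytes when the monocyte module is on).
#' @return A `vg_sim` object: `$trajectory` (tibble, one row per step) with
#'   element counts, composition fractions, mean intimal thickness (um),
#'   intimal area (mm^2; the 1-D thickness is multiplied by
#'   `equivalent_columns` elements to give an equivalent area) and
#'   cumulative event counts; `$final_grid`; `$profiles` (per-column
#'   heights at `record_profile_days`).
#' @examples
#' sim <- run_simulation(sim_config(duration = 2, mode = "1d", tau = 10), seed = 1)
#' tail(sim$trajectory, 1)
#' @export
run_simulation <- function(config, seed = NULL, initial_grid = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(initial_grid)) initial_grid <- default_initial_grid(config)
  res <- run_core(config, initial_grid)
  structure(
    list(trajectory = traj_tibble(res$out$trajectory, config),
         final_grid = grid_from_cpp(res$out$final, config$params$element_size),
         profiles = list(days = res$profile_days, heights = res$out$heights),
         clip_events = res$out$clip_events,
         config = config, seed = seed),
    class = "vg_sim"
  )
}

#' @export
print.vg_sim <- function(x, ...) {
  fin <- tail(x$trajectory, 1)
  cat(sprintf(
    "<vg_sim> %g days (%s): %d elements (SMC %.0f%%, ECM %.0f%%, monocyte %.0f%%), area %.4g mm^2\n",
    x$config$duration, x$config$mode, fin$n_total, 100 * fin$smc_fraction,
    100 * fin$ecm_fraction, 100 * fin$monocyte_fraction, fin$area_mm2))
  invisible(x)
}

#' Advance a grid by a single step
#'
#' Runs one event-loop step of `config$dt` hours starting at `t` hours on
#' the supplied grid; useful for stepwise inspection and for controlled
#' event experiments via the probability overrides.
#'
#' @param grid A `vg_grid`.
#' @param t Start time of the step, hours.
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A list with the advanced `grid` and a one-row `events` tibble of
#'   the step's event counts.
#' @export
sim_step <- function(grid, t, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cfg1 <- config
  cfg1$duration <- config$dt / 24
  cfg1$record_profile_days <- numeric(0)
  res <- run_core(cfg1, grid, start_h = t)
  mat <- res$out$trajectory
  colnames(mat) <- traj_metrics
  d <- tibble::as_tibble(mat)
  events <- tibble::tibble(
    divisions = diff(d$cum_divisions), apoptoses = diff(d$cum_apoptoses),
    influx = diff(d$cum_influx), ecm_scheduled = diff(d$cum_ecm_scheduled),
    ecm_burst = diff(d$cum_ecm_burst), ecm_degraded = diff(d$cum_ecm_degraded),
    insertions = diff(d$cum_insertions), removals = diff(d$cum_removals))
  list(grid = grid_from_cpp(res$out$final, config$params$element_size),
       events = events)
}

#' Run an ensemble of independent simulations
#'
#' Repeats [run_simulation()] with independent seeds derived from
#' `base_seed` and aggregates the trajectories pointwise (mean and SD per
#' metric per time), the Monte-Carlo analogue of averaging the growth
#' curves over many grafts.
#'
#' @param config A [sim_config()].
#' @param n_runs Number of independent runs (>= 1).
#' @param base_seed Integer seed for the whole ensemble.
#' @return A `vg_ensemble`: `$summary` (long tibble: `time_days`, `metric`,
#'   `mean`, `sd`), `$finals` (one row per run with the day-final metrics),
#'   `$n_runs`, `$config`.
#' @examples
#' ens <- run_ensemble(sim_config(duration = 2, mode = "1d", tau = 10),
#'                     n_runs = 5, base_seed = 1)
#' dplyr::filter(ens$summary, metric == "area_mm2", time_days == 2)
#' @export
run_ensemble <- function(config, n_runs, base_seed = 1) {
  stopifnot(inherits(config, "sim_config"), n_runs >= 1)
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  acc <- NULL; acc2 <- NULL; nobs <- NULL
  finals <- vector("list", n_runs)
  times <- NULL
  for (i in seq_len(n_runs)) {
    sim <- run_simulation(config, seed = seeds[i])
    m <- as.matrix(sim$trajectory[, -1])
    if (is.null(acc)) {
      times <- sim$trajectory$time_days
      acc <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
      acc2 <- acc; nobs <- acc
    }
    ok <- !is.na(m)
    m0 <- ifelse(ok, m, 0)
    acc <- acc + m0; acc2 <- acc2 + m0^2; nobs <- nobs + ok
    finals[[i]] <- dplyr::mutate(tail(sim$trajectory, 1),
                                 run = i, seed = seeds[i], .before = 1)
  }
  mean_m <- acc / nobs
  var_m <- pmax(acc2 / nobs - mean_m^2, 0) * ifelse(nobs > 1, nobs / (nobs - 1), NA)
  summary <- tibble::as_tibble(mean_m) |>
    dplyr::mutate(time_days = times) |>
    tidyr::pivot_longer(-"time_days", names_to = "metric", values_to = "mean") |>
    dplyr::left_join(
      tibble::as_tibble(sqrt(var_m)) |>
        dplyr::mutate(time_days = times) |>
        tidyr::pivot_longer(-"time_days", names_to = "metric", values_to = "sd"),
      by = c("time_days", "metric"))
  structure(
    list(summary = summary, finals = dplyr::bind_rows(finals),
         n_runs = n_runs, base_seed = base_seed, config = config),
    class = "vg_ensemble"
  )
}

#' @export
print.vg_ensemble <- function(x, ...) {
  fin <- dplyr::filter(x$summary, .data$time_days == max(.data$time_days),
                       .data$metric %in% c("area_mm2", "smc_fraction"))
  cat(sprintf("<vg_ensemble> %d runs, %g days (%s)\n", x$n_runs,
              x$config$duration, x$config$mode))
  for (i in seq_len(nrow(fin))) {
    cat(sprintf("  final %s: %.4g (SD %.3g)\n", fin$metric[i], fin$mean[i],
                fin$sd[i]))
  }
  invisible(x)
}

ensemble_final <- function(ens, metric) {
  s <- dplyr::filter(ens$summary, .data$metric == !!metric,
                     .data$time_days == max(.data$time_days))
  s$mean
}

#' Effect of the monocyte module on intimal growth
#'
#' Runs two ensembles that differ only in the monocyte module (seeding,
#' influx, and matrix-burst augmentation at division) and reports the
#' percent increase of the ensemble-mean final intimal area it causes.
#'
#' @param config A [sim_config()]; its `monocyte_module` flag is
#'   overridden in each arm.
#' @param n_runs Runs per arm.
#' @param base_seed Integer seed (shared by both arms).
#' @return A `vg_monocyte_effect`: `$percent_increase`,
#'   `$area_with`, `$area_without` (final ensemble means, mm^2), and the
#'   two `vg_ensemble` objects (`$with`, `$without`).
#' @export
monocyte_effect <- function(config, n_runs, base_seed = 1) {
  cfg_on <- config; cfg_on$monocyte_module <- TRUE
  cfg_off <- config; cfg_off$monocyte_module <- FALSE
  with_ens <- run_ensemble(cfg_on, n_runs, base_seed)
  without_ens <- run_ensemble(cfg_off, n_runs, base_seed)
  a1 <- ensemble_final(with_ens, "area_mm2")
  a0 <- ensemble_final(without_ens, "area_mm2")
  structure(
    list(percent_increase = 100 * (a1 - a0) / a0,
         area_with = a1, area_without = a0,
         with = with_ens, without = without_ens),
    class = "vg_monocyte_effect"
  )
}

#' @export
print.vg_monocyte_effect <- function(x, ...) {
  cat(sprintf(
    "<vg_monocyte_effect> final area %.4g vs %.4g mm^2: %+.1f%% with monocytes\n",
    x$area_with, x$area_without, x$percent_increase))
  invisible(x)
}

#' Focal-stenosis scenario
#'
#' Runs the 2-D algorithm under a longitudinal shear-stress field (e.g.
#' from [generate_stenosis_field()]): each column reads its shear from the
#' field at its longitudinal position, refreshed every
#' `shear_update_interval` days, and per-column intimal thickness profiles
#' are recorded at the `record_profile_days`.
#'
#' @param config A [sim_config()] with a `shear_field`.
#' @param seed Integer seed.
#' @return A `vg_sim` with an additional `$it_profile` tibble
#'   (`day`, `column`, `position_mm`, `it_um`).
#' @export
stenosis_run <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$shear_field)) {
    abort("`stenosis_run()` needs a config with a `shear_field`.")
  }
  if (config$mode != "2d") abort("`stenosis_run()` requires the 2-D mode.")
  sim <- run_simulation(config, seed = seed)
  hs <- sim$profiles$heights
  days <- sim$profiles$days
  pos_range <- range(config$shear_field$position_mm)
  col_pos <- seq(pos_range[1], pos_range[2], length.out = config$n_columns)
  sim$it_profile <- purrr::map_dfr(seq_along(days), function(i) {
    tibble::tibble(day = days[i], column = seq_len(config$n_columns),
                   position_mm = col_pos,
                   it_um = hs[i, ] * config$params$element_size)
  })
  sim
}
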
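cfg_1d <- function(...) {
  sim_config(mode = "1d", tau = 10, monocyte_module = FALSE, ...)
}

test_that("null dynamics leave the grid untouched", {
  cfg <- cfg_1d(duration = 2, override_division_prob = 0,
                override_apoptosis_prob = 0)
  g0 <- make_column_grid(c("ECM", "SMC", "ECM"))
  sim <- run_simulation(cfg, seed = 1, initial_grid = g0)
  expect_true(all(sim$trajectory$n_total == 3))
  expect_identical(as_tibble(sim$final_grid), as_tibble(g0))
  expect_true(all(sim$trajectory$cum_insertions == 0))
})

test_that("a division yields two SMC and four scheduled ECM within 48 hours", {
  n_steps <- 3 * 24
  cfg <- cfg_1d(duration = 3,
                override_division_prob = c(1, rep(0, n_steps - 1)),
                override_apoptosis_prob = 0)
  sim <- run_simulation(cfg, seed = 2)
  tr <- sim$trajectory
  expect_identical(tr$n_smc[tr$time_days == 3], 2)
  expect_identical(tr$n_ecm[tr$time_days == 3], 4)
  # first matrix element of each daughter appears 24 h after the division,
  # the second 24 h later
  expect_identical(tr$n_ecm[tr$time_days == 1], 0)
  expect_identical(tr$n_ecm[abs(tr$time_days - (25 / 24)) < 1e-9], 2)
  expect_identical(tr$n_ecm[abs(tr$time_days - (49 / 24)) < 1e-9], 4)
  expect_identical(tr$cum_divisions[n_steps + 1], 1)
})

test_that("re-division inside the production window suppresses the second ECM", {
  n_steps <- 4 * 24
  # force a second division of every SMC at hour 30 (inside the 24-48 h window)
  ov <- rep(0, n_steps); ov[1] <- 1; ov[30] <- 1
  cfg <- cfg_1d(duration = 4, override_division_prob = ov,
                override_apoptosis_prob = 0)
  sim <- run_simulation(cfg, seed = 3)
  tr <- tail(sim$trajectory, 1)
  expect_identical(tr$cum_divisions, 3)  # 1 + both daughters at hour 30
  # daughters of hour 1 produced their first ECM (hour 25) but their second
  # production was cancelled by the hour-30 division; the four hour-30
  # daughters then produce 2 each
  expect_identical(tr$n_ecm, 2 + 8)
  expect_identical(tr$n_smc, 4)
})

test_that("an apoptotic death removes the cell and its four nearest ECM", {
  g0 <- make_column_grid(c("ECM", "ECM", "SMC", "ECM", "ECM", "ECM", "ECM"))
  cfg <- cfg_1d(duration = 1, override_division_prob = 0,
                override_apoptosis_prob = 1)
  step1 <- sim_step(g0, 0, cfg, seed = 4)
  expect_identical(step1$events$apoptoses, 1)
  expect_identical(step1$events$ecm_degraded, 4)
  expect_identical(step1$events$removals, 5)
  expect_identical(n_elements(step1$grid), 2L)
  expect_identical(n_elements(step1$grid, "SMC"), 0L)
})

test_that("runs are deterministic given the seed and length-0 runs are allowed", {
  cfg <- sim_config(duration = 2, mode = "2d", n_columns = 30, tau = 1.8)
  s1 <- run_simulation(cfg, seed = 11)
  s2 <- run_simulation(cfg, seed = 11)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(as_tibble(s1$final_grid), as_tibble(s2$final_grid))
  s3 <- run_simulation(cfg, seed = 12)
  expect_false(identical(s1$trajectory, s3$trajectory))

  s0 <- run_simulation(sim_config(duration = 0, mode = "1d", tau = 10), seed = 1)
  expect_identical(nrow(s0$trajectory), 1L)
})

test_that("the element ledger balances insertions and removals exactly", {
  cfg <- sim_config(duration = 7, mode = "2d", n_columns = 40, tau = 1.8)
  tr <- run_simulation(cfg, seed = 21)$trajectory
  expect_equal(tr$n_total,
               tr$n_total[1] + tr$cum_insertions - tr$cum_removals)
  # insertions split into their sources; removals into theirs
  expect_equal(tr$cum_insertions,
               tr$cum_divisions + tr$cum_ecm_scheduled + tr$cum_ecm_burst +
                 tr$cum_influx)
  expect_equal(tr$cum_removals, tr$cum_apoptoses + tr$cum_ecm_degraded)
})

test_that("redistribution keeps adjacent columns within two elements all run", {
  cfg <- sim_config(duration = 10, mode = "2d", n_columns = 50, tau = 1.8)
  sim <- run_simulation(cfg, seed = 31)
  h <- grid_heights(sim$final_grid)
  expect_true(all(abs(diff(h)) <= 2L))
})

test_that("ensembles aggregate runs and shrink their standard error as 1/sqrt(n)", {
  cfg <- cfg_1d(duration = 7)
  e1 <- run_ensemble(cfg, n_runs = 1, base_seed = 5)
  s1 <- run_simulation(cfg, seed = e1$finals$seed[1])
  m <- dplyr::filter(e1$summary, metric == "n_total")
  expect_equal(m$mean, s1$trajectory$n_total)

  # Monte-Carlo scaling: the spread of independent ensemble means falls
  # as 1/sqrt(n_runs); measured directly over replicate ensembles
  cfg2 <- sim_config(duration = 5, mode = "2d", n_columns = 25, tau = 1.8)
  se <- vapply(c(10, 90), function(n) {
    means <- vapply(1:12, function(r) {
      ens <- run_ensemble(cfg2, n_runs = n, base_seed = 1000 * n + r)
      mean(ens$finals$area_mm2)
    }, numeric(1))
    sd(means)
  }, numeric(1))
  # a 9-fold increase in runs should shrink the SE about 3-fold
  expect_gt(se[1] / se[2], 1.6)
  expect_lt(se[1] / se[2], 6)
})

test_that("SMC fraction stays in the physiologic 15-45% band at defaults", {
  cfg <- sim_config(duration = 28, mode = "2d", n_columns = 50, tau = 1.8)
  ens <- run_ensemble(cfg, n_runs = 15, base_seed = 23)
  frac <- dplyr::filter(ens$summary, metric == "smc_fraction",
                        time_days >= 1)$mean
  expect_true(all(frac > 0.15 & frac < 0.45))
  # mean growth is non-decreasing through the first two weeks at low shear
  area <- dplyr::filter(ens$summary, metric == "area_mm2",
                        time_days <= 14)$mean
  expect_true(all(diff(area) >= 0))
})

test_that("a zeroed matrix burst and influx nullify the monocyte effect", {
  # at very high shear the normalized entry rate rounds the burst to zero
  # (N_m = [2 S(6)] = 0); with J -> 0 and no baseline monocytes the module
  # has no remaining pathway, so both arms coincide
  p0 <- vg_params(J = 1e-9, monocyte_baseline_content = 0)
  cfg <- sim_config(duration = 10, mode = "2d", n_columns = 30, tau = 60,
                    params = p0)
  me <- monocyte_effect(cfg, n_runs = 10, base_seed = 41)
  expect_lt(abs(me$percent_increase), 1)
})

test_that("the monocyte effect grows with the entry-rate amplitude J", {
  # under cross-section coupling the monocyte count scales with J, so the
  # J pathway of the module is clearly visible
  eff <- vapply(c(87.5, 175, 350), function(J) {
    cfg <- sim_config(duration = 12, mode = "2d", n_columns = 30, tau = 1.8,
                      influx_coupling = "area", params = vg_params(J = J))
    monocyte_effect(cfg, n_runs = 25, base_seed = 43)$percent_increase
  }, numeric(1))
  expect_true(all(diff(eff) > 0))
})

test_that("stenosis runs read the field, thin the throat and thicken distally", {
  field <- generate_stenosis_field(graft_length = 12, baseline_tau = 10,
                                   throat_position = 5, throat_width = 0.8,
                                   distal_recovery_length = 3)
  cfg <- sim_config(duration = 14, mode = "2d", n_columns = 48,
                    shear_field = field, record_profile_days = c(7, 14))
  # a spatially uniform field must reduce to the constant-shear lookup
  uni <- field; uni$tau <- 10
  cfg_uni <- sim_config(duration = 14, mode = "2d", n_columns = 48,
                        shear_field = uni)
  expect_equal(unique(as.vector(veingraft:::tau_star_matrix(cfg_uni))), 1)

  its <- purrr::map_dfr(1:10, function(i) {
    stenosis_run(cfg, seed = 100 + i)$it_profile
  })
  d14 <- dplyr::filter(its, day == 14)
  throat <- dplyr::filter(d14, abs(position_mm - 5) < 1)
  distal <- dplyr::filter(d14, position_mm > 6.2 & position_mm < 9.5)
  expect_gt(mean(distal$it_um), mean(throat$it_um))

  # doubling shear everywhere slows growth
  hi <- field; hi$tau <- hi$tau * 2
  cfg_hi <- sim_config(duration = 14, mode = "2d", n_columns = 48,
                       shear_field = hi)
  it_lo <- mean(purrr::map_dbl(1:8, function(i) {
    tail(run_simulation(cfg, seed = 200 + i)$trajectory$mean_it_um, 1)
  }))
  it_hi <- mean(purrr::map_dbl(1:8, function(i) {
    tail(run_simulation(cfg_hi, seed = 200 + i)$trajectory$mean_it_um, 1)
  }))
  expect_gt(it_lo, it_hi)

  short <- dplyr::filter(field, time_days <= 7)
  expect_error(
    run_simulation(sim_config(duration = 28, mode = "2d", n_columns = 10,
                              shear_field = short), seed = 1),
    "does not cover")
})

test_that("configuration validation catches bad inputs", {
  expect_error(sim_config(duration = 7, mode = "1d"), "tau")
  expect_error(sim_config(duration = 7, tau = 10, dt = 5), "divisor")
  expect_error(sim_config(duration = -1, tau = 10), "duration")
  expect_error(sim_config(tau = -2), "positive")
  expect_error(sim_config(tau = 1, shear_field = generate_stenosis_field()),
               "only one")
})

test_that("YAML configuration round-trips through read_sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "duration: 3", "mode: 1d", "tau: 10", "monocyte_module: no",
    "params:", "  A: 40", "  B: 0.2"), path)
  cfg <- read_sim_config(path)
  expect_identical(cfg$duration, 3L)
  expect_identical(cfg$mode, "1d")
  expect_false(cfg$monocyte_module)
  expect_equal(cfg$params$A, 40)
  expect_equal(cfg$params$B, 0.2)
})
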
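test_that("Poiseuille shear has the 4muQ/piR^3 form and scalings", {
  expect_equal(poiseuille_shear(Q = 0, R = 0.2), 0)
  # cubic radius scaling: doubling R divides shear by 8
  expect_equal(poiseuille_shear(1, 0.2) / poiseuille_shear(1, 0.4), 8)
  # algebraic identity: Q chosen so 4 mu Q / (pi R^3) = 10 dynes/cm^2
  R <- 0.1
  Q <- 10 * pi * R^3 / (4 * 0.035)
  expect_equal(poiseuille_shear(Q, R, mu = 0.035), 10, tolerance = 1e-12)
  expect_error(poiseuille_shear(1, 0), "positive")
  expect_error(poiseuille_shear(1, 0.1, mu = -1), "positive")
  expect_error(poiseuille_shear(-1, 0.1), "non-negative")
})

test_that("labeling surfaces decay exponentially in time with the fitted constants", {
  p <- default_params
  for (ts in c(0.18, 1, 1.4)) {
    # amplitude at t = 0 is A (resp. E) times the shear factor
    expect_equal(brdu_fraction(ts, 0, p), 44 * shear_factor(ts, p))
    expect_equal(tunel_fraction(ts, 0, p), 5 * shear_factor(ts, p))
    # one time constant decays by e^-1
    expect_equal(brdu_fraction(ts, 1 / p$B, p) / brdu_fraction(ts, 0, p),
                 exp(-1), tolerance = 1e-12)
    expect_equal(tunel_fraction(ts, 1 / p$F, p) / tunel_fraction(ts, 0, p),
                 exp(-1), tolerance = 1e-12)
  }
  t <- c(0, 1, 5, 20, 100)
  expect_true(all(diff(brdu_fraction(1, t, p)) < 0))
  expect_lt(brdu_fraction(1, 1e4, p), 1e-12)
  expect_lt(tunel_fraction(1, 1e4, p), 1e-12)
  expect_error(brdu_fraction(-1, 0), "tau_star")
  expect_error(brdu_fraction(1, -1), "non-negative")
})

test_that("forward labeling model is monotone and matches a population Monte-Carlo", {
  expect_equal(label_fraction_forward(0), 0)
  p_grid <- seq(0, 0.04, by = 0.002)
  expect_true(all(diff(label_fraction_forward(p_grid)) > 0))
  expect_error(label_fraction_forward(-0.1), "0, 1")
  expect_error(label_fraction_forward(1), "0, 1")
  set.seed(101)
  for (p in c(0.001, 0.005, 0.01)) {
    reps <- replicate(10, mc_label_fraction(p, 1e4))
    se <- sd(reps) / sqrt(10)  # SE of the mean ~ one 1e5-cell simulation
    expect_lt(abs(label_fraction_forward(p) - mean(reps)), 3 * se + 1e-9)
    # near-linearity at small p: within the (1 + T_B p) growth correction
    expect_lt(abs(label_fraction_forward(p) - 2000 * p) / (2000 * p), 24 * p + 1e-9)
  }
})

test_that("division-probability inversion is the exact inverse of the forward model", {
  expect_equal(mean_division_prob(0), 0)
  b <- seq(0, 40, by = 2)
  p <- mean_division_prob(b)
  expect_true(all(diff(p) > 0))
  expect_equal(label_fraction_forward(p), b, tolerance = 1e-12)
  # closed form at defaults: p = b/(2000 - 24 b)
  expect_equal(mean_division_prob(30), 30 / (2000 - 24 * 30), tolerance = 1e-12)
  expect_error(mean_division_prob(100), "0, 100")
  expect_warning(mean_division_prob(60), "ceiling")
})

test_that("apoptosis inversion applies the same correlation with T_D", {
  expect_equal(mean_apoptosis_prob(0), 0)
  tp <- c(1, 5, 15, 30)
  expect_true(all(diff(mean_apoptosis_prob(tp)) > 0))
  # with T_D = T_B the two inversions are structurally identical
  expect_equal(mean_apoptosis_prob(tp), mean_division_prob(tp))
  # a different residence time changes the growth-dilution term only
  p2 <- vg_params(T_D = 12)
  g12 <- mean_apoptosis_prob(10, p2)
  expect_equal(label_fraction_forward(g12, T_B = 12), 10, tolerance = 1e-12)
})

test_that("spatial normalizer matches quadrature and concentrates mass", {
  c0 <- spatial_normalizer(0.01, IT = 0.1, decay = 27.3)
  q <- integrate(function(x) c0 * exp(-27.3 * x), 0, 0.1)$value
  expect_equal(q / 0.1, 0.01, tolerance = 1e-9)
  # vanishing decay recovers the uniform profile
  expect_equal(spatial_normalizer(0.01, 0.1, 1e-12), 0.01, tolerance = 1e-9)
  expect_gt(spatial_normalizer(0.01, 0.1, 5), 0.01)
  expect_error(spatial_normalizer(0.01, -1, 5), "IT")
  expect_error(spatial_normalizer(0.01, 0.1, 0), "decay")
})

test_that("division probability falls with depth and conserves the spatial mean", {
  p <- default_params
  es <- p$element_size / 1000
  for (n in c(5, 12, 50)) {
    IT <- n * es
    d <- (seq_len(n) - 0.5) * es
    prob <- division_prob_at(1, 3, d, IT, p)
    expect_true(all(diff(prob) < 0))  # deepest elements divide least
    mean_p <- mean_division_prob(brdu_fraction(1, 3, p), p)
    expect_lt(abs(mean(prob) - mean_p) / mean_p, 0.01)
    expect_gt(prob[1], mean_p)  # luminal element above the spatial mean
  }
  expect_error(division_prob_at(1, 3, d_lumen = 0.2, IT = 0.1, p), "d_lumen")
  expect_true(all(division_prob_at(1, 0, (1:50 - 0.5) * es, 50 * es, p) <= 1))
})

test_that("apoptosis probability falls with distance from the outer wall", {
  p <- default_params
  es <- p$element_size / 1000
  n <- 10
  IT <- n * es
  d <- (seq_len(n) - 0.5) * es
  prob <- apoptosis_prob_at(1, 3, d, IT, p)
  expect_true(all(diff(prob) < 0))
  mean_p <- mean_apoptosis_prob(tunel_fraction(1, 3, p), p)
  expect_lt(abs(mean(prob) - mean_p) / mean_p, 0.01)
  # no TUNEL positivity, no apoptosis
  expect_lt(max(apoptosis_prob_at(1, 1e4, d, IT, p)), 1e-15)
  expect_error(apoptosis_prob_at(1, 3, d_outer = 0.2, IT = 0.1, p), "d_outer")
})

test_that("monocyte influx shares the labeling surface's time and shear form", {
  p <- default_params
  expect_equal(monocyte_influx(1, 0, p), 175 * shear_factor(1, p))
  expect_equal(monocyte_influx(0.18, 1 / p$K, p) / monocyte_influx(0.18, 0, p),
               exp(-1), tolerance = 1e-12)
  expect_lt(monocyte_influx(1, 1e4, p), 1e-12)
  # normalization: unit drive at the reference rate, decaying in time
  expect_equal(monocyte_norm(0.18, 0, p), shear_factor(0.18, p))
  expect_equal(monocyte_norm(0.18, 10, p, "same_time"),
               monocyte_norm(0.18, 0, p))
  expect_lt(monocyte_norm(0.18, 10, p), monocyte_norm(0.18, 0, p))
})

test_that("matrix burst count rounds 2 m_norm to the nearest integer, halves up", {
  m <- seq(0, 2, by = 0.2)
  expect_identical(matrix_burst_count(m),
                   c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_identical(matrix_burst_count(1), 2L)   # two ECM per daughter cell
  expect_identical(matrix_burst_count(0.75), 2L)  # half rounds up
  expect_error(matrix_burst_count(-0.1), "non-negative")
})

test_that("simulation core computes the same kinetics as the R functions", {
  p <- default_params
  for (ts in c(0.18, 1, 1.4)) {
    for (t in c(0, 3.5, 14)) {
      IT <- 0.084
      chk <- veingraft:::cpp_kinetics_check(ts, t, IT, unclass(p))
      expect_equal(chk[["brdu"]], brdu_fraction(ts, t, p), tolerance = 1e-12)
      expect_equal(chk[["tunel"]], tunel_fraction(ts, t, p), tolerance = 1e-12)
      expect_equal(chk[["p_div_mean"]],
                   mean_division_prob(brdu_fraction(ts, t, p), p),
                   tolerance = 1e-12)
      expect_equal(chk[["p_apop_mean"]],
                   mean_apoptosis_prob(tunel_fraction(ts, t, p), p),
                   tolerance = 1e-12)
      expect_equal(chk[["cstar"]],
                   spatial_normalizer(chk[["p_div_mean"]], IT, p$D),
                   tolerance = 1e-12)
      expect_equal(chk[["gstar"]],
                   spatial_normalizer(chk[["p_apop_mean"]], IT, p$H),
                   tolerance = 1e-12)
      expect_equal(chk[["influx"]], monocyte_influx(ts, t, p), tolerance = 1e-12)
    }
  }
})

test_that("shear response presets behave and the inverse form is available", {
  expect_equal(shear_factor(1, "exponential"), exp(-1))
  expect_equal(shear_factor(2, "inverse"), 0.5)
  p_inv <- vg_params(shear_response = "inverse")
  expect_equal(brdu_fraction(2, 0, p_inv), 22)
  expect_error(shear_factor(0), "positive")
})
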
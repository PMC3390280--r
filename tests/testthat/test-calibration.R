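test_that("diameter-cell conversion follows the spherical cubic law", {
  expect_equal(diameter_to_cells(4.57, 1000), 5e7, tolerance = 0.02)
  expect_equal(diameter_to_cells(4.57, 500), 1e8, tolerance = 0.02)
  expect_equal(diameter_to_cells(14, 1000), (pi / 6) * 14^3 * 1e6,
               tolerance = 1e-12)
  expect_equal(diameter_to_cells(28, 1000) / diameter_to_cells(14, 1000), 8,
               tolerance = 1e-12)
  expect_equal(cells_to_diameter(diameter_to_cells(9.3)), 9.3,
               tolerance = 1e-12)
})

test_that("breast Gompertz timing fit solves the two-point stage constraint", {
  cfg <- breast_config()
  fit <- fit_breast_gompertz(cfg, b = 1e12)
  # independent oracle: root-find mu on the closed-form time difference
  mu_oracle <- uniroot(function(mu) {
    p <- gompertz_params(1e12, mu)
    gompertz_time_to_size(fit$N_pT2, p) -
      gompertz_time_to_size(fit$N_pT1, p) - cfg$dt_pT1_pT2
  }, c(1e-5, 1e-2), tol = 1e-12)$root
  expect_equal(fit$mu, mu_oracle, tolerance = 1e-8)
  expect_equal(fit$mu, 9.5e-4, tolerance = 0.01)
  expect_equal(fit$t_pT2 - fit$t_pT1, cfg$dt_pT1_pT2, tolerance = 1e-9)
  expect_lt(fit$t_pT2, fit$t_pT4size)
  expect_error(fit_breast_gompertz(cfg, b = 1e9), "exceed")
  expect_error(fit_breast_gompertz(breast_config(D_pT1 = 14, D_pT2 = 14.000001,
                                                 D_pT4 = 60), 1e12),
               NA)  # nearly equal diameters still define a (tiny) mu
})

test_that("m calibration reproduces its target and scales linearly with it", {
  p <- hepato_params()
  cal <- hepato_ms_calibration()
  # round trip: rebuild the cascade with the calibrated m
  casc <- metastatic_cascade(p, cal$cfg, hepato_circ(), horizon = 1150)
  achieved <- colonies_above(casc$registries[[1L]], 4.6e7, 1110)
  expect_equal(achieved, cal$target, tolerance = 1e-6)
  # doubling the target doubles m (counts are linear in m)
  iks2 <- iks_params(gamma = 2 * 5.3e-8, alpha = 0.663)
  cal2 <- calibrate_m_to_iks("MS", p, iks2, hepato_circ(), grid_dt = 2)
  cal1 <- calibrate_m_to_iks("MS", p, iks_params(), hepato_circ(),
                             grid_dt = 2)
  expect_equal(cal2$m / cal1$m, 2, tolerance = 1e-6)
})

test_that("pT1 normalization is an exact round trip and orders stage probabilities", {
  cfg <- breast_config()
  b <- 1e12
  fit <- fit_breast_gompertz(cfg, b)
  gcfg <- generation_config("MS", m = 1e-6, alpha_d = 2 / 3)
  casc <- metastatic_cascade(fit$params, gcfg, circulation_params(),
                             horizon = fit$t_pT4size + 60, grid_dt = 2)
  reg <- casc$registries[[1L]]
  thr <- diameter_to_cells(cfg$D_visible, cfg$v_cell_met)
  scale <- normalize_to_pT1(reg, thr, fit$t_pT1, cfg$p_norm)
  expect_equal(formation_probability(reg, thr, fit$t_pT1,
                                     rate_scale = scale),
               0.011, tolerance = 1e-9)
  P <- vapply(c(fit$t_pT1, fit$t_pT2, fit$t_pT4size),
              function(t) formation_probability(reg, thr, t,
                                                rate_scale = scale),
              numeric(1))
  expect_true(all(diff(P) > 0))
})

# Exact invariance is impossible: the maximal size b is fixed in cells, so
# rescaling cell volumes shifts the stage sizes relative to the asymptote.
# The claim under test is the qualitative one: no noteworthy shift.
test_that("scaling both cell volumes together barely shifts normalized probabilities", {
  res <- lapply(c(1, 2), function(f) {
    cfg <- breast_config(v_cell_primary = 1000 * f, v_cell_met = 1000 * f)
    b <- 1e12
    fit <- fit_breast_gompertz(cfg, b)
    gcfg <- generation_config("MS", m = 1e-6, alpha_d = 2 / 3)
    casc <- metastatic_cascade(fit$params, gcfg, circulation_params(),
                               horizon = fit$t_pT4size + 60, grid_dt = 2)
    reg <- casc$registries[[1L]]
    thr <- diameter_to_cells(cfg$D_visible, cfg$v_cell_met)
    scale <- normalize_to_pT1(reg, thr, fit$t_pT1, cfg$p_norm)
    formation_probability(reg, thr, fit$t_pT2, rate_scale = scale)
  })
  expect_lt(abs(res[[1]] - res[[2]]), 0.1)
})

test_that("the summary grid has the documented layout and sane probabilities", {
  tb <- breast_table("MS", dissemination = "V23", variants = c("P", "A"),
                     pairs = "1_1", n_courses = 500, seed = 3)
  expect_equal(nrow(tb), 2L)
  expect_named(tb, c("engine", "dissemination", "variant", "v_primary",
                     "v_met", "P_pT2_pct", "P_pT4_pct", "mean_t1st_months",
                     "mean_t1st_before_pT1_months", "fwhm_fraction",
                     "n_courses", "seed"))
  expect_true(all(tb$P_pT2_pct >= 0 & tb$P_pT2_pct <= 100))
  expect_true(all(tb$P_pT2_pct <= tb$P_pT4_pct))
  # reduced metastatic growth makes visible metastases rarer at pT2
  expect_lt(tb$P_pT2_pct[tb$variant == "A"],
            tb$P_pT2_pct[tb$variant == "P"])
  # the truncated statistic can only be earlier than the full mean
  expect_true(all(tb$mean_t1st_before_pT1_months <= tb$mean_t1st_months))
})

test_that("halving the metastatic cell volume raises the visibility threshold to 1e8", {
  cfg <- breast_config(v_cell_met = 500)
  expect_equal(diameter_to_cells(cfg$D_visible, cfg$v_cell_met), 1e8,
               tolerance = 0.02)
})
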
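test_that("course sampling satisfies the Poisson identity P = 1 - exp(-Lambda)", {
  casc <- hepato_ms_cascade()
  int1 <- casc$intensities[[1L]]
  n <- 10000
  # scale the rate down so the identity is tested away from saturation
  scale <- 1.5 / sum(int1$lambda)
  ens <- sample_courses(int1, n, seed = 11, rate_scale = scale)
  Lambda <- attr(ens, "lambda_total")
  expect_equal(Lambda, 1.5, tolerance = 1e-12)
  p_hat <- mean(ens$n_events >= 1)
  p_exp <- 1 - exp(-Lambda)
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(p_hat - p_exp), 3 * se)
  # event counts are Poisson with the right mean
  expect_lt(abs(mean(ens$n_events) - Lambda),
            3 * sqrt(Lambda / n))
})

test_that("course sampling is bit-identical under a fixed seed and independent otherwise", {
  casc <- hepato_ms_cascade()
  int1 <- casc$intensities[[1L]]
  a <- sample_courses(int1, 500, seed = 123)
  b <- sample_courses(int1, 500, seed = 123)
  expect_identical(a$n_events, b$n_events)
  expect_identical(a$first_time, b$first_time)
  c <- sample_courses(int1, 500, seed = 124)
  expect_false(identical(a$first_time, c$first_time))
})

test_that("all-zero intensity yields courses without events", {
  cfg0 <- generation_config("MS", m = 0)
  c0 <- metastatic_cascade(hepato_params(), cfg0, hepato_circ(),
                           horizon = 600)
  ens <- sample_courses(c0$intensities[[1L]], 50, seed = 1)
  expect_true(all(ens$n_events == 0))
  expect_true(all(is.na(ens$first_time)))
  expect_error(first_colonization_stats(ens), "no course")
})

test_that("mean first-colonization time matches the analytic minimum of the Poisson process", {
  casc <- hepato_ms_cascade()
  int1 <- casc$intensities[[1L]]
  n <- 10000
  ens <- sample_courses(int1, n, seed = 5)
  ft <- ens$first_time[!is.na(ens$first_time)]
  # E[T1 | >= 1 event] by quadrature over the survival function
  grid_dt <- attr(int1, "grid_dt")
  cum <- cumsum(int1$lambda)
  tt <- int1$t0 + grid_dt
  dens <- int1$lambda / grid_dt * exp(-(cum - int1$lambda / 2))
  E_T1 <- sum((tt - grid_dt / 2) * dens * grid_dt) /
    (1 - exp(-cum[length(cum)]))
  expect_lt(abs(mean(ft) - E_T1), 3 * sd(ft) / sqrt(length(ft)))
})

test_that("first-colonization statistics degrade sensibly to a single bin", {
  df <- data.frame(t0 = c(100, 101), mean_t = c(100.5, 101.5),
                   lambda = c(3, 0))
  int <- metacascade:::new_intensity(df, order = 1L, grid_dt = 1,
                                     circ = circulation_params(),
                                     total_influx = 3, pool_end = 0)
  ens <- sample_courses(int, 4000, seed = 2)
  st <- first_colonization_stats(ens, bin_width = 1)
  expect_equal(st$mean_months * 30.4375, 100.4, tolerance = 0.01)
  expect_lt(st$fwhm_fraction, 0.02)   # width collapses to the bin scale
})

test_that("formation probability: analytic agrees with ensemble counting", {
  cal <- hepato_ms_calibration()
  casc <- metastatic_cascade(hepato_params(), cal$cfg, hepato_circ(),
                             horizon = 1150)
  p_ana <- formation_probability(casc$registries[[1L]], 4.6e7, 1110)
  # ensemble: count courses with >= 1 colonizer seeded early enough to be
  # visible by day 1110
  int1 <- casc$intensities[[1L]]
  cutoff <- 1110 - approx(log(casc$traj$cells), casc$traj$t_start,
                          xout = log(4.6e7))$y
  n <- 10000
  ens <- sample_courses(int1, n, seed = 31, t_max = cutoff)
  p_mc <- mean(ens$n_events >= 1)
  se <- sqrt(p_ana * (1 - p_ana) / n)
  expect_lt(abs(p_mc - p_ana), 3 * se + 0.01)
})

test_that("for small maximal sizes MS metastasizes early and rarely, GDR late and often", {
  m_ms <- hepato_ms_calibration()$m
  m_gdr <- hepato_gdr_calibration()$m
  small_b <- c(1e6, 1e7)
  ms <- first_met_scan(small_b, "MS", T_D_ref = 10, m = m_ms,
                       alpha_d = 1, horizon = 5000, n_courses = 1500,
                       seed = 2, grid_dt = 5)
  gdr <- first_met_scan(small_b, "GDR", T_D_ref = 10, m = m_gdr,
                        alpha_d = 2 / 3, horizon = 5000, n_courses = 1500,
                        seed = 2, grid_dt = 5)
  expect_true(all(ms$mean_T1stM_months < gdr$mean_T1stM_months))
  expect_true(all(ms$P_formation < gdr$P_formation))
  # the MS first-metastasis time is nearly constant in this regime
  expect_lt(abs(diff(ms$mean_T1stM_months)) / ms$mean_T1stM_months[1L],
            0.15)
})

test_that("first-metastasis scan shows the documented size dependence", {
  scan <- first_met_scan(b_grid = c(1e6, 1e7, 1e8, 1e9, 1e10, 1e11, 1e12),
                         engine = "MS", T_D_ref = 10, m = 1.4e-5,
                         alpha_d = 1, horizon = 4500, n_courses = 500,
                         seed = 3, grid_dt = 5)
  expect_equal(nrow(scan), 7L)
  # formation probability reaches ~1 around b = 1e9 cells
  expect_gt(scan$P_formation[scan$b == 1e9], 0.8)
  expect_gt(scan$P_formation[scan$b == 1e10], 0.99)
  expect_lt(scan$P_formation[scan$b == 1e6], 0.5)
  # mean first-metastasis time decreases beyond 1e9
  late <- scan$mean_T1stM_months[scan$b >= 1e9]
  expect_true(all(diff(late) < 0))
})

test_that("the decreasing branch is captured by the doubling-time-like fit", {
  b_grid <- 10^seq(9, 12.5, by = 0.5)
  scan <- first_met_scan(b_grid, engine = "MS", T_D_ref = 10, m = 1.4e-5,
                         alpha_d = 1, horizon = 4500, n_courses = 500,
                         seed = 4, grid_dt = 5)
  fit <- attr(scan, "fit")
  expect_false(is.null(fit))
  expect_gt(fit$fm_beta, 1)
  pred <- -(fit$fm_scale / fit$mu_ref) *
    log(1 - log(fit$fm_beta) / log(scan$b)) / 30.4375
  rel <- abs(pred / scan$mean_T1stM_months - 1)
  expect_lt(stats::median(rel), 0.15)
})
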
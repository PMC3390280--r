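test_that("circulation step matches its closed forms", {
  circ <- circulation_params(T_env = 1, c_frac = 1e-4)
  z <- circulation_step(0, 0, circ, T = 4.07)
  expect_equal(z$surviving_pool, 0)
  expect_equal(z$surviving_new, 0)
  expect_equal(z$colonizers, 0)

  s <- circulation_step(1, 0, circ, T = 4.07)
  expect_equal(s$surviving_pool, exp(-4.07), tolerance = 1e-12)
  expect_equal(s$colonizers, 1e-4 * (1 - exp(-4.07)), tolerance = 1e-12)

  n <- circulation_step(0, 1, circ, T = 4.07)
  expect_equal(n$surviving_new, (1 - exp(-4.07)) / 4.07, tolerance = 1e-12)
  expect_error(circulation_step(-1, 0, circ, 1), "negative")
})

test_that("circulation step agrees with an event-level Monte Carlo", {
  set.seed(42)
  circ <- circulation_params(T_env = 1.7, c_frac = 0.3)
  T <- 2.3
  N <- 2e5
  # old pool: exponential lifetimes from the interval start
  life_old <- rexp(N, rate = 1 / circ$T_env)
  surv_old <- mean(life_old > T)
  exit_old <- life_old[life_old <= T]
  # influx: uniform entry plus exponential lifetime
  entry <- runif(N, 0, T)
  exit_new_t <- entry + rexp(N, rate = 1 / circ$T_env)
  surv_new <- mean(exit_new_t > T)
  z <- circulation_step(1, 1, circ, T)
  se <- 3 / sqrt(N)
  expect_lt(abs(z$surviving_pool - surv_old), se)
  expect_lt(abs(z$surviving_new - surv_new), se)
  mc_mean <- mean(c(exit_old, exit_new_t[exit_new_t <= T]))
  expect_lt(abs(z$mean_colonization_time - mc_mean), 3 * T / sqrt(N))
})

test_that("colonizers are conserved: c_frac of everything that left circulation", {
  cal <- hepato_ms_calibration()
  casc <- hepato_ms_cascade()
  int1 <- casc$intensities[[1L]]
  circ <- hepato_circ()
  influx <- attr(int1, "total_influx")
  expect_equal(sum(int1$lambda),
               circ$c_frac * (influx - attr(int1, "pool_end")),
               tolerance = 1e-9)
  # with a grid reaching past the last generation the pool fully drains,
  # so colonizers equal c_frac of every disseminated cell
  int_full <- first_order_intensity(casc$traj, circ)
  expect_lt(attr(int_full, "pool_end") / attr(int_full, "total_influx"),
            1e-8)
  expect_equal(sum(int_full$lambda),
               circ$c_frac * sum(casc$traj$disseminated),
               tolerance = 1e-8)
})

test_that("first-order cascade matches an event-driven Monte Carlo", {
  p <- gompertz_params(1e5, 0.01)
  circ <- circulation_params(T_env = 1, c_frac = 0.05)
  cfg <- generation_config("MS", m = 2e-3, alpha_d = 1)
  horizon <- 300
  traj <- ms_trajectory(p, cfg, horizon)
  int1 <- first_order_intensity(traj, circ, grid_dt = 1, horizon = horizon)
  set.seed(99)
  reps <- 400
  tot <- t100 <- numeric(reps)
  for (r in seq_len(reps)) {
    n_dis <- rpois(nrow(traj), traj$disseminated)
    entry <- rep(traj$t_start, n_dis) + runif(sum(n_dis)) *
      rep(traj$T_G, n_dis)
    death <- entry + rexp(sum(n_dis), rate = 1 / circ$T_env)
    col <- death[runif(sum(n_dis)) < circ$c_frac]
    tot[r] <- sum(col <= horizon)
    t100[r] <- sum(col <= 100)
  }
  expect_lt(abs(sum(int1$lambda) - mean(tot)), 3 * sd(tot) / sqrt(reps))
  expect_lt(abs(sum(int1$lambda[int1$t0 + 1 <= 100]) - mean(t100)),
            3 * sd(t100) / sqrt(reps) + sum(int1$lambda[int1$t0 == 99]))
})

test_that("halving the reporting grid changes visible-colony counts by < 1%", {
  cal <- hepato_ms_calibration()
  p <- hepato_params()
  counts <- vapply(c(1, 0.5), function(dt) {
    casc <- metastatic_cascade(p, cal$cfg, hepato_circ(), horizon = 1150,
                               grid_dt = dt)
    colonies_above(casc$registries[[1L]], 4.6e7, 1110)
  }, numeric(1))
  expect_lt(abs(counts[2] / counts[1] - 1), 0.01)
})

test_that("excision cuts dissemination but lets the circulating pool resolve", {
  p <- gompertz_params(1e6, 0.01)
  cfg <- generation_config("MS", m = 1e-3, alpha_d = 1)
  circ <- circulation_params(T_env = 1, c_frac = 0.1)
  traj <- ms_trajectory(p, cfg, 400)
  full <- first_order_intensity(traj, circ, horizon = 400)
  exc <- first_order_intensity(traj, circ, horizon = 400,
                               excision_time = 200)
  # identical until the excision
  expect_equal(exc$lambda[exc$t0 < 199], full$lambda[full$t0 < 199],
               tolerance = 1e-12)
  # residual pool resolves within a few lifetimes, then nothing colonizes
  expect_gt(sum(exc$lambda[exc$t0 >= 200 & exc$t0 < 210]), 0)
  expect_equal(sum(exc$lambda[exc$t0 > 230]), 0, tolerance = 1e-12)
  # totals: c_frac times the cells disseminated before the cut
  cum <- metacascade:::cumulative_dissemination(traj, c(0, 200))
  expect_equal(sum(exc$lambda), circ$c_frac * diff(cum), tolerance = 1e-6)
})

test_that("an excision scenario freezes dissemination but not colony growth", {
  cal <- hepato_ms_calibration()
  p <- hepato_params()
  casc <- metastatic_cascade(p, cal$cfg, hepato_circ(), horizon = 2200)
  casc_exc <- metastatic_cascade(p, cal$cfg, hepato_circ(), horizon = 2200,
                                 excision_time = 678)
  m_full <- metastatic_mass(casc$registries[[1L]], 2150)
  m_exc <- metastatic_mass(casc_exc$registries[[1L]], 2150)
  expect_gt(m_full / m_exc, 10)    # order-of-magnitude reduction
  # colonies seeded before excision keep growing afterwards
  expect_gt(metastatic_mass(casc_exc$registries[[1L]], 2150),
            metastatic_mass(casc_exc$registries[[1L]], 1000))
})

test_that("metastatic mass and colony counts behave monotonically", {
  casc <- hepato_ms_cascade()
  reg <- casc$registries[[1L]]
  tt <- c(600, 900, 1110, 1350)
  expect_true(all(diff(metastatic_mass(reg, tt)) > 0))
  expect_true(all(diff(colonies_above(reg, 4.6e7, tt)) > 0))
  # threshold 1 at late time counts every colonizer seeded so far
  expect_equal(colonies_above(reg, 1, 1e4), sum(reg$cohorts$count),
               tolerance = 1e-12)
  # nothing is visible before the first seed has had time to grow
  expect_equal(colonies_above(reg, 4.6e7, 300), 0)
  # zero dissemination means zero metastatic mass
  cfg0 <- generation_config("MS", m = 0)
  c0 <- metastatic_cascade(hepato_params(), cfg0, hepato_circ(),
                           horizon = 1200)
  expect_equal(metastatic_mass(c0$registries[[1L]], 1100), 0)
  expect_true(is.na(mass_parity_time(c0$registries[[1L]], c0$traj)))
})

test_that("mass parity time decreases strictly with the dissemination rate", {
  cal <- hepato_ms_calibration()
  p <- hepato_params()
  parity <- vapply(c(0.5, 1, 2, 4), function(f) {
    cfg <- cal$cfg; cfg$m <- cal$m * f
    casc <- metastatic_cascade(p, cfg, hepato_circ(), horizon = 1700,
                               grid_dt = 2)
    mass_parity_time(casc$registries[[1L]], casc$traj)
  }, numeric(1))
  expect_true(all(diff(parity) < 0))
})
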
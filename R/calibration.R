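#' Convert tumour diameter to cell count
#'
#' Spherical tumour of diameter `D` millimetres composed of cells of volume
#' `v_cell` cubic micrometres: `cells = (pi/6) D^3 1e9 / v_cell`.
#'
#' @param D Diameter in mm (vectorised, non-negative).
#' @param v_cell Cell volume in um^3 (default 1000).
#' @return Number of cells.
#' @examples
#' diameter_to_cells(4.57)   # ~5e7: the visibility threshold
#' @export
diameter_to_cells <- function(D, v_cell = 1000) {
  stopifnot(is.numeric(D), all(D >= 0), is.numeric(v_cell), v_cell > 0)
  (pi / 6) * D^3 * 1e9 / v_cell
}

#' @rdname diameter_to_cells
#' @param x Number of cells.
#' @export
cells_to_diameter <- function(x, v_cell = 1000) {
  stopifnot(is.numeric(x), all(x >= 0))
  (6 * x * v_cell / (pi * 1e9))^(1 / 3)
}

#' Breast-cancer registry configuration
#'
#' Stage summaries of the breast-cancer registry application: mean stage
#' diameters, the mean pT1-to-pT2 progression time inferred from mean ages
#' at diagnosis (57 vs 58.1 years), the observed visible-metastasis
#' prevalence at pT1 used for normalization, and the visibility diameter.
#'
#' @param v_cell_primary,v_cell_met Cell volumes in um^3 (default 1000).
#' @param D_pT1,D_pT2,D_pT4 Mean stage diameters in mm.
#' @param dt_pT1_pT2 Mean pT1-to-pT2 progression time in days.
#' @param p_norm Probability of a visible metastasis at pT1 (0.011).
#' @param D_visible Visibility diameter of a metastasis in mm.
#' @param b_interval Interval of maximal tumour sizes (cells) averaged over
#'   in the summary table.
#' @param b_scan Interval spanned by probability-vs-size scans.
#' @return An object of class `breast_config`.
#' @export
breast_config <- function(v_cell_primary = 1000, v_cell_met = 1000,
                          D_pT1 = 14, D_pT2 = 28, D_pT4 = 60,
                          dt_pT1_pT2 = 1.1 * 365.25,
                          p_norm = 0.011, D_visible = 4.57,
                          b_interval = c(7.5e11, 1.25e12),
                          b_scan = c(5e10, 1e13)) {
  stopifnot(D_pT1 < D_pT2, D_pT2 < D_pT4, dt_pT1_pT2 > 0,
            p_norm > 0, p_norm < 1, D_visible > 0)
  structure(list(v_cell_primary = v_cell_primary, v_cell_met = v_cell_met,
                 D_pT1 = D_pT1, D_pT2 = D_pT2, D_pT4 = D_pT4,
                 dt_pT1_pT2 = dt_pT1_pT2, p_norm = p_norm,
                 D_visible = D_visible, b_interval = b_interval,
                 b_scan = b_scan),
            class = "breast_config")
}

#' Fit Gompertz timing to breast-cancer stage summaries
#'
#' Given the maximal size `b`, solves for the growth constant `mu` such that
#' a Gompertzian tumour needs exactly the registry's mean pT1-to-pT2
#' progression time to grow from the pT1 to the pT2 cell count:
#' \deqn{\mu = \log\frac{1 - \log N_1/\log b}{1 - \log N_2/\log b} /
#'       \Delta t.}
#' Stage times are measured from a single cell at `t = 0`; the pT4 time is
#' the time the primary reaches the 60 mm cell count (size-based).
#'
#' @param cfg A [breast_config()].
#' @param b Maximal tumour size in cells; must exceed the pT2 cell count.
#' @return List with `params` (a [gompertz_params()]), `mu`, stage cell
#'   counts `N_pT1`, `N_pT2`, `N_pT4`, and stage times `t_pT1`, `t_pT2`,
#'   `t_pT4size` in days.
#' @export
fit_breast_gompertz <- function(cfg, b) {
  stopifnot(inherits(cfg, "breast_config"))
  N1 <- diameter_to_cells(cfg$D_pT1, cfg$v_cell_primary)
  N2 <- diameter_to_cells(cfg$D_pT2, cfg$v_cell_primary)
  N4 <- diameter_to_cells(cfg$D_pT4, cfg$v_cell_primary)
  if (N1 >= N2) stop("degenerate stage sizes: pT1 must be smaller than pT2")
  if (b <= N2) stop("'b' must exceed the pT2 cell count")
  lb <- log(b)
  mu <- log((1 - log(N1) / lb) / (1 - log(N2) / lb)) / cfg$dt_pT1_pT2
  p <- gompertz_params(b, mu)
  list(params = p, mu = mu,
       N_pT1 = N1, N_pT2 = N2, N_pT4 = N4,
       t_pT1 = gompertz_time_to_size(N1, p),
       t_pT2 = gompertz_time_to_size(N2, p),
       t_pT4size = if (N4 < b) gompertz_time_to_size(N4, p) else NA_real_)
}

#' Calibrate the dissemination coefficient against the reference model
#'
#' Root-finds the dissemination coefficient `m` such that the expected
#' number of visible colonies (at least `x_min` cells) produced by the
#' generation-model cascade at `t_eval` equals the first-order count of the
#' colony-size reference model.  Because the cascade's colony counts scale
#' exactly linearly in `m`, the root is found in closed form from a single
#' probe run.
#'
#' @param engine `"MS"` or `"GDR"`.
#' @param p A [gompertz_params()] object.
#' @param iks An [iks_params()] object (the calibration target).
#' @param circ A [circulation_params()] object.
#' @param alpha_d Dissemination exponent of the generation model.
#' @param d_i Initial doubling fraction.
#' @param t_eval Evaluation time in days since initiation (day 1110: 432
#'   days after a diagnosis 678 days after initiation).
#' @param x_min Visibility threshold in cells.
#' @param grid_dt Cascade grid width in days.
#' @param dissemination_clock Passed to [generation_config()].
#' @param m_probe Probe coefficient for the linear solve.
#'
#' @return List of class `m_calibration`: `m`, the calibrated
#'   [generation_config()] (`cfg`), `target` and `achieved` visible-colony
#'   counts, and `residual`.
#' @export
calibrate_m_to_iks <- function(engine = c("MS", "GDR"), p,
                               iks = iks_params(),
                               circ = circulation_params(),
                               alpha_d = if (engine == "MS") 1 else 2 / 3,
                               d_i = 2 / 3, t_eval = 1110, x_min = 4.6e7,
                               grid_dt = 1,
                               dissemination_clock = "per_generation",
                               m_probe = 1e-6) {
  engine <- match.arg(engine)
  force(alpha_d)
  eps <- if (engine == "GDR") fit_gdr_decrement(p, d_i = d_i) else 0
  cfg <- generation_config(engine, d_i = d_i, m = m_probe,
                           alpha_d = alpha_d, epsilon = eps,
                           dissemination_clock = dissemination_clock)
  horizon <- t_eval + 30 * circ$T_env
  casc <- metastatic_cascade(p, cfg, circ, horizon = horizon,
                             grid_dt = grid_dt)
  probe_count <- colonies_above(casc$registries[[1L]], x_min, t_eval)
  if (probe_count <= 0) stop("probe cascade produced no visible colonies")
  target <- iks_colony_count(t_eval, x_min, iks, p, order = 1L)
  m <- m_probe * target / probe_count
  cfg$m <- m
  achieved <- probe_count * m / m_probe
  structure(list(m = m, cfg = cfg, engine = engine, target = target,
                 achieved = achieved, residual = achieved - target,
                 t_eval = t_eval, x_min = x_min),
            class = "m_calibration")
}

#' @export
print.m_calibration <- function(x, ...) {
  cat(sprintf("<m_calibration> %s engine: m = %.4g\n", x$engine, x$m))
  cat(sprintf("  target %.4g visible colonies (>= %.3g cells at day %.0f), residual %.2g\n",
              x$target, x$x_min, x$t_eval, x$residual))
  invisible(x)
}

#' Normalize the combined dissemination-colonization rate at pT1
#'
#' Scales the combined rate `m * c_frac` so that the probability of a
#' visible metastasis at the pT1 stage time equals the registry prevalence
#' `p_norm`.  Since the expected visible-colony count is linear in the rate,
#' the scale is `-log(1 - p_norm) / Lambda_vis(t_pT1)`.
#'
#' @param registry A `colony_registry` built from an unscaled cascade.
#' @param threshold Visibility threshold in cells.
#' @param t_pT1 pT1 stage time in days since initiation.
#' @param p_norm Target probability (default 0.011).
#' @return The rate scale factor (dimensionless).
#' @export
normalize_to_pT1 <- function(registry, threshold, t_pT1, p_norm = 0.011) {
  lam <- colonies_above(registry, threshold, t_pT1)
  if (lam <= 0)
    stop("no visible colonies expected at pT1: cannot normalize")
  -log(1 - p_norm) / lam
}

breast_row_grid <- function() {
  rows <- rbind(
    expand.grid(dissemination = "V",   variant = "P",
                pair = c("1_1", "2_1"), stringsAsFactors = FALSE),
    expand.grid(dissemination = c("V23", "V13"), variant = c("P", "A"),
                pair = c("1_1", "2_1", "1_0.5"), stringsAsFactors = FALSE))
  rows[order(match(rows$dissemination, c("V", "V23", "V13")),
             match(rows$variant, c("P", "A")),
             match(rows$pair, c("1_1", "2_1", "1_0.5"))), ]
}

#' Metastasis-formation probabilities and first-colonization times for
#' breast-cancer stages
#'
#' Reproduces the registry summary grid: for each dissemination exponent
#' (volume, surface, diameter), metastasis growth characteristic
#' (`P` = like the primary, `A` = artificially reduced, inheriting the
#' seeding generation's state) and primary/metastatic cell-volume pair, the
#' probability of a visible metastasis at the pT2 time and at the pT4 size,
#' and the mean time of the first colonizing cell — normalized so that the
#' probability of a visible metastasis at pT1 is `cfg$p_norm` — averaged
#' over maximal sizes `b_values` with `n_courses` randomized courses each.
#'
#' @param engine `"MS"` or `"GDR"`.
#' @param cfg A [breast_config()].
#' @param b_values Maximal sizes averaged over (defaults to the ends and
#'   midpoint of `cfg$b_interval`).
#' @param dissemination Subset of `c("V", "V23", "V13")` to compute.
#' @param variants Subset of `c("P", "A")`.
#' @param pairs Subset of `c("1_1", "2_1", "1_0.5")` (primary and
#'   metastatic cell volume in units of 1000 um^3).
#' @param n_courses Randomized courses per `b`.
#' @param seed RNG seed.
#' @param grid_dt Cascade grid width in days.
#' @param normalization `"per_b"` (each maximal size has its own rate
#'   scale; default) or `"global"` (one scale, fitted at the central `b`).
#' @param d_i Initial doubling fraction.
#'
#' @return Data frame with one row per configuration: `engine`,
#'   `dissemination`, `variant`, `v_primary`, `v_met`, `P_pT2_pct`,
#'   `P_pT4_pct`, `mean_t1st_months` (from initiation),
#'   `mean_t1st_before_pT1_months` (restricted to colonizations before
#'   pT1), `fwhm_fraction`, `n_courses`, `seed`.
#' @export
breast_table <- function(engine = c("MS", "GDR"), cfg = breast_config(),
                         b_values = NULL,
                         dissemination = c("V", "V23", "V13"),
                         variants = c("P", "A"),
                         pairs = c("1_1", "2_1", "1_0.5"),
                         n_courses = 2000, seed = 1L, grid_dt = 2,
                         normalization = c("per_b", "global"),
                         d_i = 2 / 3,
                         dissemination_clock = "per_generation") {
  engine <- match.arg(engine)
  normalization <- match.arg(normalization)
  stopifnot(inherits(cfg, "breast_config"))
  if (is.null(b_values))
    b_values <- c(cfg$b_interval[1L], mean(cfg$b_interval),
                  cfg$b_interval[2L])
  grid <- breast_row_grid()
  grid <- grid[grid$dissemination %in% dissemination &
               grid$variant %in% variants & grid$pair %in% pairs, ]
  alpha_of <- c(V = 1, V23 = 2 / 3, V13 = 1 / 3)
  out <- vector("list", nrow(grid))
  global_scale <- NULL
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    pr <- strsplit(g$pair, "_")[[1L]]
    v_p <- as.numeric(pr[1L]) * 1000
    v_m <- as.numeric(pr[2L]) * 1000
    row_cfg <- cfg
    row_cfg$v_cell_primary <- v_p
    row_cfg$v_cell_met <- v_m
    thr <- diameter_to_cells(cfg$D_visible, v_m)
    acc <- list(P2 = 0, P4 = 0, mt = 0, mt_pre = 0, fwhm = 0, nb = 0)
    for (ib in seq_along(b_values)) {
      b <- b_values[ib]
      fit <- fit_breast_gompertz(row_cfg, b)
      p <- fit$params
      eps <- if (engine == "GDR") fit_gdr_decrement(p, d_i = d_i) else 0
      gcfg <- generation_config(engine, d_i = d_i, m = 1e-6,
                                alpha_d = alpha_of[[g$dissemination]],
                                epsilon = eps,
                                dissemination_clock = dissemination_clock)
      variant <- if (g$variant == "P") "primary_like"
                 else if (engine == "GDR") "gdr_inherited_d"
                 else "ms_inherited_TG"
      horizon <- max(fit$t_pT4size, fit$t_pT2) + 60
      casc <- metastatic_cascade(p, gcfg, circulation_params(),
                                 horizon = horizon, grid_dt = grid_dt,
                                 variant = variant)
      reg <- casc$registries[[1L]]
      scale <- if (normalization == "per_b") {
        normalize_to_pT1(reg, thr, fit$t_pT1, cfg$p_norm)
      } else {
        if (is.null(global_scale))
          global_scale <- normalize_to_pT1(reg, thr, fit$t_pT1, cfg$p_norm)
        global_scale
      }
      P2 <- formation_probability(reg, thr, fit$t_pT2, rate_scale = scale)
      P4 <- formation_probability(reg, thr, fit$t_pT4size,
                                  rate_scale = scale)
      ens <- sample_courses(casc$intensities[[1L]], n_courses,
                            seed = seed + 1000L * r + ib,
                            rate_scale = scale)
      st <- first_colonization_stats(ens)
      pre <- ens$first_time[!is.na(ens$first_time) &
                              ens$first_time <= fit$t_pT1]
      acc$P2 <- acc$P2 + P2; acc$P4 <- acc$P4 + P4
      acc$mt <- acc$mt + st$mean_months
      acc$mt_pre <- acc$mt_pre +
        if (length(pre)) mean(pre) / 30.4375 else NA_real_
      acc$fwhm <- acc$fwhm + st$fwhm_fraction
      acc$nb <- acc$nb + 1
    }
    out[[r]] <- data.frame(
      engine = engine, dissemination = g$dissemination,
      variant = g$variant, v_primary = v_p, v_met = v_m,
      P_pT2_pct = 100 * acc$P2 / acc$nb,
      P_pT4_pct = 100 * acc$P4 / acc$nb,
      mean_t1st_months = acc$mt / acc$nb,
      mean_t1st_before_pT1_months = acc$mt_pre / acc$nb,
      fwhm_fraction = acc$fwhm / acc$nb,
      n_courses = n_courses, seed = seed,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
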
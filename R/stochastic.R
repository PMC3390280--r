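#' Sample randomized integer courses of disease
#'
#' Draws `n` independent disease courses from a colonization intensity:
#' per course the integer number of colonizing cells in each time bin is
#' Poisson with the bin's expected value, and the first colonization time is
#' the earliest event (continuous within its bin, since the intensity is
#' piecewise constant).  Internally the Poisson field is sampled through its
#' sufficient statistics — total event count and the conditional first-event
#' time — which is distributionally identical to drawing every bin.
#'
#' @param intensity A `colonization_intensity`.
#' @param n Number of courses.
#' @param seed RNG seed (integer) for reproducibility.
#' @param rate_scale Multiplier applied to the intensity (used by the
#'   normalized breast workflows); default 1.
#' @param t_max Only events up to this time (days) are considered; defaults
#'   to the full grid.
#'
#' @return A `course_ensemble`: data frame with columns `course`,
#'   `n_events`, `first_time` (days, `NA` when the course has no event),
#'   with attributes `lambda_total` and `seed`.
#' @export
sample_courses <- function(intensity, n, seed = NULL, rate_scale = 1,
                           t_max = NULL) {
  stopifnot(inherits(intensity, "colonization_intensity"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  grid_dt <- attr(intensity, "grid_dt")
  lam <- intensity$lambda * rate_scale
  t_hi <- intensity$t0 + grid_dt
  if (!is.null(t_max)) {
    frac <- pmin(pmax((t_max - intensity$t0) / grid_dt, 0), 1)
    lam <- lam * frac
    t_hi <- pmin(t_hi, t_max)
  }
  cum <- cumsum(lam)
  Lambda <- cum[length(cum)]
  n_events <- stats::rpois(n, Lambda)
  first_time <- rep(NA_real_, n)
  has <- n_events >= 1L
  if (any(has) && Lambda > 0) {
    # first of N iid events with cdf cum(t)/Lambda
    v <- stats::runif(sum(has))
    q <- Lambda * (1 - (1 - v)^(1 / n_events[has]))
    first_time[has] <- stats::approx(c(0, cum), c(intensity$t0[1L], t_hi),
                                     xout = q, ties = "ordered")$y
  }
  structure(data.frame(course = seq_len(n), n_events = n_events,
                       first_time = first_time),
            class = c("course_ensemble", "data.frame"),
            lambda_total = Lambda, seed = seed)
}

#' @export
print.course_ensemble <- function(x, ...) {
  cat(sprintf("<course_ensemble> %d courses, Lambda = %.4g\n",
              nrow(x), attr(x, "lambda_total")))
  cat(sprintf("  %.1f%% with >= 1 colonization; mean first time %.1f days\n",
              100 * mean(x$n_events >= 1),
              mean(x$first_time, na.rm = TRUE)))
  invisible(x)
}

#' Probability that a visible metastasis has formed
#'
#' Analytic formation probability: colonies form as a Poisson field, so the
#' probability that at least one colony has reached `threshold` cells by
#' `t_eval` is \eqn{1 - e^{-\Lambda}}, with \eqn{\Lambda} the expected
#' number of such colonies.
#'
#' @param registry A `colony_registry` (or list of registries) whose cohort
#'   counts are the Poisson expectations.
#' @param threshold Visibility threshold in cells.
#' @param t_eval Evaluation time in days since initiation.
#' @param rate_scale Multiplier on the expected counts (normalization).
#' @return Probability in `[0, 1]`.
#' @export
formation_probability <- function(registry, threshold, t_eval,
                                  rate_scale = 1) {
  lam <- colonies_above(registry, threshold, t_eval) * rate_scale
  1 - exp(-lam)
}

#' Mean and spread of the first-colonization time
#'
#' @param ensemble A `course_ensemble` from [sample_courses()].
#' @param bin_width Histogram bin width in days used for the full width at
#'   half maximum (default one month).
#'
#' @return List with `mean_months` (mean first-colonization time over
#'   courses with at least one event, months of 30.4375 days),
#'   `fwhm_fraction` (full width at half maximum of the first-time histogram
#'   divided by the mean), `n_events_courses`, and the `histogram`.
#' @export
first_colonization_stats <- function(ensemble, bin_width = 30.4375) {
  stopifnot(inherits(ensemble, "course_ensemble"))
  ft <- ensemble$first_time[!is.na(ensemble$first_time)]
  if (length(ft) == 0L) stop("no course experienced a colonization event")
  breaks <- seq(floor(min(ft) / bin_width) * bin_width,
                max(ft) + bin_width, by = bin_width)
  h <- graphics::hist(ft, breaks = breaks, plot = FALSE)
  fwhm <- hist_fwhm(h$mids, h$counts)
  m <- mean(ft)
  list(mean_months = m / 30.4375,
       fwhm_fraction = fwhm / m,
       n_event_courses = length(ft),
       histogram = h)
}

# full width at half maximum of a binned curve, linearly interpolated
hist_fwhm <- function(mids, counts) {
  if (length(mids) < 2L) return(mids[1L] * 0 + diff(range(mids)) + 0)
  peak <- max(counts)
  half <- peak / 2
  above <- which(counts >= half)
  i1 <- above[1L]; i2 <- above[length(above)]
  left <- if (i1 == 1L) mids[1L] else
    stats::approx(counts[c(i1 - 1L, i1)], mids[c(i1 - 1L, i1)], half)$y
  right <- if (i2 == length(counts)) mids[length(mids)] else
    stats::approx(counts[c(i2 + 1L, i2)], mids[c(i2 + 1L, i2)], half)$y
  right - left
}

#' Scan of the first-metastasis time against maximal tumour size
#'
#' For each maximal size `b` in `b_grid`, rebuilds the primary trajectory
#' and colonization intensity (the growth constant `mu` is held fixed at the
#' value giving the requested initial doubling time at a reference size of
#' `1e11` cells), samples randomized courses, and records the mean
#' first-colonization time and the formation probability.  The decreasing
#' branch of the mean-time curve is then fitted with
#' \deqn{f(b) = -\frac{\gamma_f}{\mu}\,\log(1 - \log\beta_f/\log b),}
#' the same functional form that links `mu` to the initial doubling time.
#'
#' @param b_grid Maximal sizes in cells (between 1e5 and 1e13).
#' @param engine `"MS"` or `"GDR"`.
#' @param T_D_ref Initial doubling time (days) at the reference size 1e11.
#' @param m,alpha_d Dissemination coefficient and exponent.
#' @param d_i Initial doubling fraction.
#' @param circ A [circulation_params()] object.
#' @param horizon Follow-up in days (default about 25 years).
#' @param n_courses Courses per grid point (2000-10000 in the validated
#'   workflows).
#' @param seed RNG seed.
#' @param grid_dt Cascade grid width in days.
#'
#' @return A `first_met_scan` object: data frame with columns `b`,
#'   `mean_T1stM_months`, `P_formation`, `n_courses`; attribute `fit` holds
#'   the `FirstMetFit` list (`fm_scale`, `fm_beta`, `mu_ref`) or `NULL` if
#'   no decreasing branch was fittable.
#' @export
first_met_scan <- function(b_grid, engine = c("MS", "GDR"), T_D_ref = 10,
                           m, alpha_d = 1, d_i = 2 / 3,
                           circ = circulation_params(),
                           horizon = 25 * 365.25, n_courses = 2000,
                           seed = 1L, grid_dt = 2) {
  engine <- match.arg(engine)
  stopifnot(all(b_grid >= 1e5), all(b_grid <= 1e13))
  b_ref <- 1e11
  mu <- -log(1 - log(2) / log(b_ref)) / T_D_ref
  rows <- vector("list", length(b_grid))
  for (i in seq_along(b_grid)) {
    b <- b_grid[i]
    p <- gompertz_params(b, mu)
    cfg <- if (engine == "MS") {
      generation_config("MS", d_i = d_i, m = m, alpha_d = alpha_d)
    } else {
      generation_config("GDR", d_i = d_i, m = m, alpha_d = alpha_d,
                        epsilon = fit_gdr_decrement(p, d_i = d_i))
    }
    traj <- run_engine(p, cfg, horizon)
    int1 <- first_order_intensity(traj, circ, grid_dt = grid_dt,
                                  horizon = horizon)
    ens <- sample_courses(int1, n_courses, seed = seed + i)
    ft <- ens$first_time
    rows[[i]] <- data.frame(
      b = b,
      mean_T1stM_months = mean(ft, na.rm = TRUE) / 30.4375,
      P_formation = 1 - exp(-attr(ens, "lambda_total")),
      n_courses = n_courses)
  }
  out <- do.call(rbind, rows)
  fit <- fit_first_met_curve(out$b, out$mean_T1stM_months * 30.4375, mu)
  structure(out, class = c("first_met_scan", "data.frame"),
            fit = fit, mu_ref = mu, engine = engine)
}

# Fit f(b) = -fm_scale/mu * log(1 - log(fm_beta)/log(b)) to the decreasing
# branch (days in, days out); returns NULL when no branch qualifies.
fit_first_met_curve <- function(b, mean_days, mu) {
  ok <- is.finite(mean_days)
  b <- b[ok]; y <- mean_days[ok]
  if (length(b) < 4L) return(NULL)
  o <- order(b); b <- b[o]; y <- y[o]
  i0 <- which.max(y)
  if (length(b) - i0 < 3L) return(NULL)
  bb <- b[i0:length(b)]; yy <- y[i0:length(y)]
  if (any(diff(yy) > 0)) {
    # keep the longest strictly decreasing suffix
    inc <- which(diff(yy) > 0)
    cut <- max(inc) + 1L
    bb <- bb[cut:length(bb)]; yy <- yy[cut:length(yy)]
    if (length(bb) < 4L) return(NULL)
  }
  fit <- try(minpack.lm::nlsLM(
    yy ~ -(g / mu) * log(1 - lbeta / log(bb)),
    start = list(g = 1, lbeta = 0.5 * log(min(bb))),
    lower = c(g = 1e-8, lbeta = 1e-8),
    upper = c(g = Inf, lbeta = 0.999 * log(min(bb))),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  cf <- stats::coef(fit)
  list(fm_scale = as.numeric(cf[["g"]]),
       fm_beta = exp(as.numeric(cf[["lbeta"]])),
       mu_ref = mu, fit = fit)
}

#' @export
print.first_met_scan <- function(x, ...) {
  cat(sprintf("<first_met_scan> %s engine, %d sizes, mu = %.4g /day\n",
              attr(x, "engine"), nrow(x), attr(x, "mu_ref")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  f <- attr(x, "fit")
  if (!is.null(f))
    cat(sprintf("  decreasing-branch fit: fm_scale = %.4g, fm_beta = %.4g\n",
                f$fm_scale, f$fm_beta))
  invisible(x)
}
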
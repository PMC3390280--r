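#' Per-generation configuration of the discrete growth engines
#'
#' Bundles the branching fractions and engine choice used by
#' [ms_trajectory()] and [gdr_trajectory()].  At every generation each tumour
#' cell either doubles (fraction `d`), dies (fraction `a`) or disseminates
#' into circulation, with `a + d + m = 1`; only the doubling fraction drives
#' growth, so the tumour multiplies by `2 d` per generation.
#'
#' @param engine `"MS"` (metabolic stagnation: the generation time stretches
#'   as `log(b)/log(b/x)` while fractions stay constant) or `"GDR"`
#'   (generation-dependent rates: constant generation time, with the doubling
#'   excess `2 d - 1` decaying geometrically by `epsilon` per generation and
#'   apoptosis absorbing the difference).
#' @param d_i Initial doubling fraction, in (1/2, 1].
#' @param m Dissemination coefficient.  The expected number of cells shed
#'   into circulation during a generation of a tumour with `x` cells is
#'   `m * x^alpha_d` (under the alternative `"per_time"` clock, multiplied
#'   by the generation-time stretch factor; see below).
#' @param alpha_d Dissemination exponent: 1 for shedding proportional to
#'   volume, 2/3 for surface, 1/3 for diameter.
#' @param epsilon GDR per-generation fractional decrease of the doubling
#'   excess `2 d - 1`, in `[0, 1)`; ignored by the MS engine.
#' @param d_f Doubling-fraction floor for the GDR engine, in `[1/2, d_i]`.
#' @param T_G0 Base generation time in days; if `NULL` it is derived from the
#'   growth law as `generation_time(initial_doubling_time(p), d_i)` when the
#'   engine runs.
#' @param dissemination_clock Whether shedding occurs once per mitotic
#'   generation regardless of its length (`"per_generation"`, the default:
#'   dissemination is coupled to the generation's fate split) or is
#'   proportional to the time the generation takes (`"per_time"`: cells
#'   leave at a constant per-day rate `m x^alpha_d / T_G0`, so a stretched
#'   MS generation sheds more).  The two coincide for the GDR engine, whose
#'   generation time is constant.
#'
#' @return An object of class `generation_config`.
#' @export
generation_config <- function(engine = c("MS", "GDR"),
                              d_i = 2 / 3,
                              m = 0,
                              alpha_d = 1,
                              epsilon = 0,
                              d_f = 0.5,
                              T_G0 = NULL,
                              dissemination_clock = c("per_generation", "per_time")) {
  engine <- match.arg(engine)
  dissemination_clock <- match.arg(dissemination_clock)
  stopifnot(is.numeric(d_i), length(d_i) == 1L,
            is.numeric(m), length(m) == 1L, m >= 0,
            is.numeric(alpha_d), length(alpha_d) == 1L,
            alpha_d > 0, alpha_d <= 1,
            is.numeric(epsilon), length(epsilon) == 1L,
            epsilon >= 0, epsilon < 1,
            is.numeric(d_f), length(d_f) == 1L)
  if (d_i <= 0.5 || d_i > 1) stop("'d_i' must lie in (1/2, 1]")
  if (d_f < 0.5 || d_f > d_i) stop("'d_f' must lie in [1/2, d_i]")
  if (alpha_d == 1 && d_i + m > 1)
    stop("fractions violate a + d + m = 1: d_i + m exceeds 1")
  if (!is.null(T_G0)) stopifnot(is.numeric(T_G0), length(T_G0) == 1L, T_G0 > 0)
  structure(list(engine = engine, d_i = d_i, m = m, alpha_d = alpha_d,
                 epsilon = epsilon, d_f = d_f, T_G0 = T_G0,
                 dissemination_clock = dissemination_clock),
            class = "generation_config")
}

#' @export
print.generation_config <- function(x, ...) {
  cat(sprintf("<generation_config> engine = %s\n", x$engine))
  cat(sprintf("  d_i = %.4g, m = %.4g, alpha_d = %.4g (clock: %s)\n",
              x$d_i, x$m, x$alpha_d, x$dissemination_clock))
  if (x$engine == "GDR")
    cat(sprintf("  epsilon = %.4g per generation, d_f = %.4g\n",
                x$epsilon, x$d_f))
  if (!is.null(x$T_G0)) cat(sprintf("  T_G0 = %.4g days\n", x$T_G0))
  invisible(x)
}

resolve_T_G0 <- function(p, cfg) {
  if (!is.null(cfg$T_G0)) cfg$T_G0
  else generation_time(initial_doubling_time(p), cfg$d_i)
}

dissemination_of_step <- function(x, d, T_G, T_G0, cfg) {
  base <- cfg$m * x^cfg$alpha_d
  if (cfg$dissemination_clock == "per_time") base * T_G / T_G0 else base
}

make_trajectory <- function(rec, p, cfg, T_G0, x_end, t_end) {
  df <- as.data.frame(rec)
  structure(df,
            class = c("trajectory", "data.frame"),
            params = p, config = cfg, T_G0 = T_G0,
            x_end = x_end, t_end = t_end)
}

#' Metabolic-stagnation (MS) growth trajectory
#'
#' Discrete generation engine approximating Gompertzian growth by stretching
#' the generation time: step `n` lasts `T_G0 * log(b)/log(b/x_n)` and
#' multiplies the tumour by `2 d`.  Fractions `d`, `a`, `m` stay constant.
#' Stepping stops at `horizon` or when the next generation would exceed the
#' asymptotic size `b` (growth is then frozen; the diverging generation time
#' makes this practically unreachable).
#'
#' @param p A [gompertz_params()] object.
#' @param cfg A [generation_config()] with `engine = "MS"`.
#' @param horizon Simulation horizon in days.
#' @param x0 Starting size in cells (default one cell).
#'
#' @return A `trajectory`: a data frame with one row per generation and
#'   columns `generation`, `t_start`, `T_G`, `cells`, `d`, `a`, `m_frac` and
#'   `disseminated` (expected cells entering circulation during the step).
#' @export
ms_trajectory <- function(p, cfg, horizon, x0 = 1) {
  stopifnot(inherits(p, "gompertz_params"), inherits(cfg, "generation_config"),
            cfg$engine == "MS", is.numeric(horizon), horizon > 0,
            x0 >= 1)
  T_G0 <- resolve_T_G0(p, cfg)
  d <- cfg$d_i
  lb <- log(p$b)
  n_guess <- ceiling(lb / log(2 * d)) + 16L
  gen <- t_start <- T_G <- cells <- dis <- numeric(n_guess)
  x <- x0; t <- 0; i <- 0L
  while (t < horizon && x < p$b && 2 * d * x <= p$b) {
    i <- i + 1L
    if (i > length(cells)) {  # horizon-limited before saturation
      grow <- function(v) c(v, numeric(length(v)))
      gen <- grow(gen); t_start <- grow(t_start); T_G <- grow(T_G)
      cells <- grow(cells); dis <- grow(dis)
    }
    Tg <- T_G0 * lb / log(p$b / x)
    gen[i] <- i - 1L; t_start[i] <- t; T_G[i] <- Tg; cells[i] <- x
    dis[i] <- dissemination_of_step(x, d, Tg, T_G0, cfg)
    t <- t + Tg
    x <- 2 * d * x
  }
  idx <- seq_len(i)
  m_frac <- ifelse(cells[idx] > 0, dis[idx] / cells[idx], 0)
  rec <- list(generation = gen[idx], t_start = t_start[idx], T_G = T_G[idx],
              cells = cells[idx], d = rep(d, i), a = 1 - d - m_frac,
              m_frac = m_frac, disseminated = dis[idx])
  make_trajectory(rec, p, cfg, T_G0, x_end = x, t_end = t)
}

#' Generation-dependent-rates (GDR) growth trajectory
#'
#' Discrete engine with constant generation time `T_G0` in which the doubling
#' excess decays geometrically, `2 d_n - 1 = (2 d_i - 1)(1 - epsilon)^n`
#' (floored so that `d_n >= d_f`), and apoptosis absorbs the decrease so that
#' `a_n + d_n + m = 1`.  With `epsilon` fitted via [fit_gdr_decrement()] the
#' trajectory saturates at the Gompertz asymptote `b`.
#'
#' @inheritParams ms_trajectory
#' @param cfg A [generation_config()] with `engine = "GDR"`.
#' @param start_generation Index of the first generation (default 0).  A
#'   positive value starts the decay deeper in the schedule, which is how
#'   metastases inheriting the doubling rate of their seeding generation are
#'   grown.
#'
#' @return A `trajectory`, see [ms_trajectory()].
#' @export
gdr_trajectory <- function(p, cfg, horizon, x0 = 1, start_generation = 0L) {
  stopifnot(inherits(p, "gompertz_params"), inherits(cfg, "generation_config"),
            cfg$engine == "GDR", is.numeric(horizon), horizon > 0,
            x0 >= 1, start_generation >= 0L)
  T_G0 <- resolve_T_G0(p, cfg)
  n_steps <- max(1L, ceiling(horizon / T_G0))
  n_idx <- start_generation + seq_len(n_steps) - 1L
  e_i <- 2 * cfg$d_i - 1
  e_f <- 2 * cfg$d_f - 1
  e_n <- pmax(e_i * (1 - cfg$epsilon)^n_idx, e_f)
  d_n <- (1 + e_n) / 2
  growth <- cumprod(c(1, 1 + e_n))          # length n_steps + 1
  cells <- x0 * growth[seq_len(n_steps)]
  x_end <- x0 * growth[n_steps + 1L]
  t_start <- (seq_len(n_steps) - 1L) * T_G0
  dis <- cfg$m * cells^cfg$alpha_d          # clocks coincide: T_G constant
  m_frac <- ifelse(cells > 0, dis / cells, 0)
  rec <- list(generation = n_idx, t_start = t_start,
              T_G = rep(T_G0, n_steps), cells = cells,
              d = d_n, a = 1 - d_n - m_frac, m_frac = m_frac,
              disseminated = dis)
  make_trajectory(rec, p, cfg, T_G0, x_end = x_end, t_end = n_steps * T_G0)
}

#' Fit the GDR doubling-excess decrement to a Gompertz asymptote
#'
#' Finds the per-generation fractional decrease `epsilon` of the doubling
#' excess such that the GDR trajectory's asymptotic size
#' \eqn{\exp\{\sum_n \log(1 + (2 d_i - 1)(1-\epsilon)^n)\}} equals `b`.
#' Requires `d_f = 1/2` (a higher floor never saturates).
#'
#' @param p A [gompertz_params()] object supplying the target asymptote `b`.
#' @param d_i Initial doubling fraction.
#' @param d_f Doubling-fraction floor; must be 1/2 for a finite asymptote.
#'
#' @return The decrement `epsilon` (dimensionless fraction per generation).
#' @export
fit_gdr_decrement <- function(p, d_i = 2 / 3, d_f = 0.5) {
  stopifnot(inherits(p, "gompertz_params"))
  if (d_f != 0.5)
    stop("'d_f' must be 1/2: a floor above 1/2 gives unbounded growth")
  if (d_i <= d_f || d_i > 1) stop("'d_i' must lie in (1/2, 1]")
  target <- log(p$b)
  asym <- function(eps) gdr_log_asymptote(d_i, eps)
  lo <- 1e-8; hi <- 0.9
  if (asym(lo) < target)
    stop("no root: even epsilon ~ 0 undershoots log(b)")
  if (asym(hi) > target)
    stop("no root: epsilon near 1 still overshoots log(b)")
  stats::uniroot(function(e) asym(e) - target, c(lo, hi), tol = 1e-12)$root
}

# log asymptotic size of a GDR trajectory: sum_n log(1 + e_i (1-eps)^n).
# Terms below 1e-9 are summed analytically (geometric tail, log1p(e) ~ e).
gdr_log_asymptote <- function(d_i, eps) {
  e_i <- 2 * d_i - 1
  if (eps <= 0) return(Inf)
  n_max <- ceiling(log(e_i / 1e-9) / -log1p(-eps))
  n_max <- min(n_max, 2e6)
  head_sum <- sum(log1p(e_i * (1 - eps)^(0:n_max)))
  tail_sum <- e_i * (1 - eps)^(n_max + 1) / eps
  head_sum + tail_sum
}

#' @export
print.trajectory <- function(x, ...) {
  cfg <- attr(x, "config"); p <- attr(x, "params")
  cat(sprintf("<trajectory> %s engine, %d generations to day %.1f\n",
              cfg$engine, nrow(x), attr(x, "t_end")))
  cat(sprintf("  final size %.4g cells (asymptote b = %.4g)\n",
              attr(x, "x_end"), p$b))
  cat(sprintf("  total disseminated %.4g cells\n", sum(x$disseminated)))
  invisible(x)
}

#' @export
summary.trajectory <- function(object, ...) {
  print(object)
  utils::str(utils::head(as.data.frame(object)))
  invisible(object)
}

#' @export
plot.trajectory <- function(x, log = "y", ...) {
  plot(x$t_start, x$cells, type = "s", log = log,
       xlab = "days since initiation", ylab = "cells", ...)
  invisible(x)
}

#' Tumour size along a trajectory at arbitrary times
#'
#' Interpolates the per-generation sizes geometrically within each step
#' (exponential growth at the step's own rate).  Times beyond the last step
#' return the final size; negative times return `NA`.
#'
#' @param traj A `trajectory`.
#' @param t Times in days since the trajectory's start (vectorised).
#' @return Sizes in cells.
#' @export
size_at <- function(traj, t) {
  stopifnot(inherits(traj, "trajectory"))
  tk <- c(traj$t_start, attr(traj, "t_end"))
  yk <- log(c(traj$cells, attr(traj, "x_end")))
  out <- rep(NA_real_, length(t))
  ok <- !is.na(t) & t >= 0
  if (any(ok))
    out[ok] <- exp(stats::approx(tk, yk, xout = t[ok], rule = 2)$y)
  out
}

#' Export a trajectory as a plain data frame for CSV output
#'
#' @param traj A `trajectory`.
#' @return A data frame with columns `generation`, `t_start_days`,
#'   `T_G_days`, `cells`, `d`, `a`, `m`, `disseminated`.
#' @export
trajectory_table <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  data.frame(generation = traj$generation,
             t_start_days = traj$t_start,
             T_G_days = traj$T_G,
             cells = traj$cells,
             d = traj$d, a = traj$a, m = traj$m_frac,
             disseminated = traj$disseminated)
}
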
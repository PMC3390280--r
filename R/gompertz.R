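#' Gompertz growth parameters
#'
#' Container for the two parameters of the Gompertz tumour growth law
#' \eqn{g(x) = \mu x \log(b/x)}, whose solution starting from a single cell
#' is \eqn{G(t) = b^{1 - e^{-\mu t}}}.
#'
#' @param b Asymptotic maximal tumour size in cells; must exceed 1.
#' @param mu Growth constant in 1/day; must be positive.
#'
#' @return An object of class `gompertz_params`.
#' @examples
#' hepato <- gompertz_params(b = 7.3e10, mu = 0.00286)
#' initial_doubling_time(hepato)
#' @export
gompertz_params <- function(b, mu) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (b <= 1) stop("'b' must exceed 1 cell")
  if (mu <= 0) stop("'mu' must be positive")
  structure(list(b = b, mu = mu), class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat("Gompertz growth law G(t) = b^(1 - exp(-mu t))\n")
  cat(sprintf("  b  = %.4g cells (asymptotic size)\n", x$b))
  cat(sprintf("  mu = %.4g / day  (initial doubling time %.2f days)\n",
              x$mu, initial_doubling_time(x)))
  invisible(x)
}

#' Gompertz tumour size at a given time
#'
#' Evaluates \eqn{G(t) = b^{1 - e^{-\mu t}}}, the size (in cells) of a tumour
#' that started from a single cell at `t = 0` and grows with rate
#' \eqn{g(x) = \mu x \log(b/x)}.
#'
#' @param t Time since initiation in days (vectorised, non-negative).
#' @param p A [gompertz_params()] object.
#'
#' @return Tumour size in cells, between 1 and `p$b`.
#' @export
gompertz_size <- function(t, p) {
  stopifnot(inherits(p, "gompertz_params"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be non-negative")
  exp(log(p$b) * (1 - exp(-p$mu * t)))
}

#' Time for a Gompertzian tumour to reach a given size
#'
#' Inverse of [gompertz_size()]:
#' \eqn{t(x) = -\log(1 - \log x / \log b) / \mu}.
#'
#' @param x Target size in cells (vectorised); must satisfy `1 <= x < b`.
#' @param p A [gompertz_params()] object.
#'
#' @return Time in days since initiation from a single cell.
#' @export
gompertz_time_to_size <- function(x, p) {
  stopifnot(inherits(p, "gompertz_params"), is.numeric(x))
  if (any(x < 1)) stop("'x' must be at least 1 cell")
  if (any(x >= p$b)) stop("'x' must lie below the asymptotic size 'b'")
  -log(1 - log(x) / log(p$b)) / p$mu
}

#' Initial doubling time of a Gompertzian tumour
#'
#' Time for the first doubling (1 to 2 cells),
#' \eqn{T_D = -\log(1 - \log 2/\log b)/\mu}.
#'
#' @param p A [gompertz_params()] object with `b > 2`.
#' @return Doubling time in days.
#' @export
initial_doubling_time <- function(p) {
  stopifnot(inherits(p, "gompertz_params"))
  if (p$b <= 2) stop("'b' must exceed 2 cells for a doubling time")
  gompertz_time_to_size(2, p)
}

#' Generation time for a given doubling fraction
#'
#' With only a fraction `d` of cells doubling per generation, growth per
#' generation is `2 d`; matching the initial doubling time `T_D` requires a
#' generation time \eqn{T_G = T_D \log(2d)/\log 2}.
#'
#' @param T_D Initial doubling time in days.
#' @param d Doubling fraction per generation, strictly above 1/2.
#' @return Generation time in days.
#' @export
generation_time <- function(T_D, d) {
  stopifnot(is.numeric(T_D), T_D > 0, is.numeric(d))
  if (any(d <= 0.5)) stop("'d' must exceed 1/2 for net growth")
  T_D * log(2 * d) / log(2)
}

#' Fit the Gompertz law to a growth trajectory
#'
#' Least-squares fit of \eqn{\log G(t) = \log(b)(1 - e^{-\mu t})} to the
#' per-generation sizes of a simulated [trajectory] (or any set of times and
#' sizes) in log-size space.
#'
#' @param traj A `trajectory` object from [ms_trajectory()]/[gdr_trajectory()]
#'   (resampled on a uniform time grid over its span, so that every day of
#'   growth carries the same weight regardless of the engine's step
#'   lengths), or a data frame with columns `t` and `cells` used as given.
#' @param start Optional list with starting values `b` and `mu`.
#' @param sample_dt Resampling step in days for trajectory input (default:
#'   1/400 of the trajectory span).
#'
#' @return A [gompertz_params()] object with attributes `fit` (the
#'   `nls`-style fit object) and `residual_sd` (in log-cells).
#' @export
fit_gompertz <- function(traj, start = NULL, sample_dt = NULL) {
  if (inherits(traj, "trajectory")) {
    t_end <- attr(traj, "t_end")
    if (is.null(sample_dt)) sample_dt <- t_end / 400
    tt <- seq(0, t_end, by = sample_dt)
    xx <- size_at(traj, tt)
  } else {
    stopifnot(is.data.frame(traj), all(c("t", "cells") %in% names(traj)))
    tt <- traj$t
    xx <- traj$cells
  }
  keep <- is.finite(tt) & is.finite(xx) & xx >= 1
  tt <- tt[keep]; xx <- xx[keep]
  if (length(tt) < 10L) stop("need at least 10 trajectory points for a fit")
  y <- log(xx)
  if (is.null(start)) {
    lb0 <- max(y) * 1.05
    # early log-slope ~ mu * log(b)
    i <- seq_len(max(3L, length(y) %/% 4L))
    sl <- stats::coef(stats::lm(y[i] ~ tt[i]))[2L]
    start <- list(logb = lb0, mu = max(as.numeric(sl) / lb0, 1e-6))
  } else {
    start <- list(logb = log(start$b), mu = start$mu)
  }
  fit <- minpack.lm::nlsLM(
    y ~ logb * (1 - exp(-mu * tt)),
    start = start,
    lower = c(logb = log(2), mu = 1e-10),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  out <- gompertz_params(b = exp(cf[["logb"]]), mu = cf[["mu"]])
  attr(out, "fit") <- fit
  attr(out, "residual_sd") <- stats::sd(stats::residuals(fit))
  out
}
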
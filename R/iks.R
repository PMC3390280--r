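#' Parameters of the colony-size reference model
#'
#' In the reference transport model of metastatic colony sizes, a
#' Gompertzian primary seeds colonies at rate \eqn{\beta(x) = \gamma
#' x^\alpha} (per day), and every colony grows from one cell with the same
#' Gompertz law as the primary.
#'
#' @param gamma Colonization coefficient, 1/day/cells^alpha.
#' @param alpha Fractal dissemination exponent in `[0, 1]` (fraction of
#'   tumour cells taking part in dissemination; 2/3 for surface shedding).
#' @return An object of class `iks_params`.
#' @export
iks_params <- function(gamma = 5.3e-8, alpha = 0.663) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0,
            is.numeric(alpha), length(alpha) == 1L,
            alpha >= 0, alpha <= 1)
  structure(list(gamma = gamma, alpha = alpha), class = "iks_params")
}

#' @export
print.iks_params <- function(x, ...) {
  cat(sprintf("<iks_params> beta(x) = %.4g * x^%.4g per day\n",
              x$gamma, x$alpha))
  invisible(x)
}

#' Expected colony count in the reference model
#'
#' Cumulative number of metastatic colonies of at least `x_min` cells at
#' time `t`, by adaptive quadrature of the seeding rate.  A colony seeded at
#' time `tau` has reached `x_min` by `t` iff `t - tau >= a(x_min)`, the
#' Gompertz time from one cell to `x_min`, so the first-order count is
#' \deqn{N_1(t, x_{min}) = \int_0^{t - a(x_{min})} \gamma\, G(\tau)^\alpha\,
#' d\tau.}
#' Second-order colonies are seeded by first-order colonies of size
#' \eqn{G(s-\tau)} (renewal double integral).
#'
#' @param t Evaluation time in days since tumour initiation.
#' @param x_min Size threshold in cells, `1 <= x_min < b`.
#' @param iks An [iks_params()] object.
#' @param p A [gompertz_params()] object.
#' @param order Metastatic order, 1 or 2.
#' @param rel_tol Relative quadrature tolerance.
#'
#' @return Expected number of colonies (0 when `t < a(x_min)`).
#' @export
iks_colony_count <- function(t, x_min, iks, p, order = 1L, rel_tol = 1e-6) {
  stopifnot(inherits(iks, "iks_params"), inherits(p, "gompertz_params"),
            is.numeric(t), t >= 0, is.numeric(x_min), x_min >= 1,
            x_min < p$b, order %in% c(1L, 2L))
  lag <- if (x_min > 1) gompertz_time_to_size(x_min, p) else 0
  upper <- t - lag
  if (upper <= 0) return(0)
  beta <- function(tau) iks$gamma * gompertz_size(tau, p)^iks$alpha
  if (order == 1L)
    return(stats::integrate(beta, 0, upper, rel.tol = rel_tol,
                            subdivisions = 500L)$value)
  # order 2: seeding rate at time s from order-1 colonies seeded at tau
  rate2 <- function(s) {
    vapply(s, function(si) {
      if (si <= 0) return(0)
      stats::integrate(function(tau) beta(tau) *
                         iks$gamma * gompertz_size(si - tau, p)^iks$alpha,
                       0, si, rel.tol = rel_tol * 10,
                       subdivisions = 500L)$value
    }, numeric(1))
  }
  stats::integrate(rate2, 0, upper, rel.tol = rel_tol,
                   subdivisions = 500L)$value
}
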
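#' Circulation-survival parameters for disseminated cells
#'
#' Disseminated cells survive in circulation for an exponentially distributed
#' time with mean `T_env`; on leaving circulation a fraction `c_frac`
#' colonizes a distant organ, the remainder is eliminated.
#'
#' @param T_env Mean lifetime in circulation, days.
#' @param c_frac Colonization fraction (ratio of the colonization rate to the
#'   total decay rate in circulation), in `[0, 1]`.
#' @return An object of class `circulation_params`.
#' @export
circulation_params <- function(T_env = 1, c_frac = 1e-4) {
  stopifnot(is.numeric(T_env), length(T_env) == 1L, T_env > 0,
            is.numeric(c_frac), length(c_frac) == 1L,
            c_frac >= 0, c_frac <= 1)
  structure(list(T_env = T_env, c_frac = c_frac),
            class = "circulation_params")
}

#' @export
print.circulation_params <- function(x, ...) {
  cat(sprintf("<circulation_params> T_env = %g days, c_frac = %g\n",
              x$T_env, x$c_frac))
  invisible(x)
}

#' One bookkeeping step of the circulating-cell pool
#'
#' Advances the circulating pool over an interval of length `T`.  Cells
#' already in the pool decay exponentially and survive with
#' `F = exp(-T/T_env)`; newly disseminated cells (`influx`) enter uniformly
#' over the interval and survive with `(T_env/T) (1 - exp(-T/T_env))`.  A
#' fraction `c_frac` of all cells leaving circulation colonizes; the mean
#' colonization time (days from the start of the interval) combines the
#' truncated-exponential distribution of the old pool with the
#' uniform-entry/exponential-lifetime convolution of the influx.
#'
#' @param pool Cells in circulation at the start of the interval.
#' @param influx Cells entering circulation during the interval.
#' @param circ A [circulation_params()] object.
#' @param T Interval length in days.
#'
#' @return A list with `surviving_pool`, `surviving_new`, `colonizers`
#'   (expected colonizing cells during the interval) and
#'   `mean_colonization_time`.
#' @export
circulation_step <- function(pool, influx, circ, T) {
  stopifnot(inherits(circ, "circulation_params"),
            is.numeric(pool), is.numeric(influx), is.numeric(T), T > 0)
  if (any(pool < 0) || any(influx < 0)) stop("negative cell counts")
  k <- circulation_kernel(circ, T)
  surviving_pool <- pool * k$F
  surviving_new <- influx * k$S
  elim_old <- pool * (1 - k$F)
  elim_new <- influx * (1 - k$S)
  elim <- elim_old + elim_new
  mean_t <- ifelse(elim > 0,
                   (elim_old * k$mt_old + elim_new * k$mt_new) / elim,
                   NA_real_)
  list(surviving_pool = surviving_pool,
       surviving_new = surviving_new,
       colonizers = circ$c_frac * elim,
       mean_colonization_time = mean_t)
}

# Constants of one interval of length T: survival factors and mean exit
# times of the two sub-populations.
circulation_kernel <- function(circ, T) {
  tau <- circ$T_env
  r <- T / tau
  F <- exp(-r)
  S <- (1 - F) / r                      # uniform entry over the interval
  # exit time | exit within [0, T]: old pool ~ truncated exponential
  mt_old <- tau - T * F / (1 - F)
  # influx: exit density on [0,T] is proportional to 1 - exp(-s/tau)
  mt_new <- (T^2 / 2 - tau^2 + F * (tau * T + tau^2)) / (T - tau * (1 - F))
  list(F = F, S = S, mt_old = mt_old, mt_new = mt_new)
}

# Cumulative disseminated cells of a trajectory up to each time in `edges`,
# with uniform shedding within each generation step.
cumulative_dissemination <- function(traj, edges, cutoff = NULL) {
  t0 <- traj$t_start
  Tg <- traj$T_G
  dis <- traj$disseminated
  if (!is.null(cutoff)) {
    frac <- pmin(pmax((cutoff - t0) / Tg, 0), 1)
    dis <- dis * frac
    Tg <- Tg * pmax(frac, 1e-300)       # keep density of the clipped part
  }
  vapply(edges, function(e) {
    sum(dis * pmin(pmax((e - t0) / Tg, 0), 1))
  }, numeric(1))
}

new_intensity <- function(df, order, grid_dt, circ, total_influx, pool_end) {
  structure(df, class = c("colonization_intensity", "data.frame"),
            order = order, grid_dt = grid_dt, circ = circ,
            total_influx = total_influx, pool_end = pool_end)
}

#' @export
print.colonization_intensity <- function(x, ...) {
  cat(sprintf("<colonization_intensity> order %d, %d bins of %.3g days\n",
              attr(x, "order"), nrow(x), attr(x, "grid_dt")))
  cat(sprintf("  expected colonizers %.4g (influx %.4g, residual pool %.4g)\n",
              sum(x$lambda), attr(x, "total_influx"), attr(x, "pool_end")))
  invisible(x)
}

# Chain per-bin influx through the circulating pool on a uniform grid.
# Returns the colonization intensity data frame plus the final pool.
chain_circulation <- function(influx, edges, circ, grid_dt) {
  n <- length(influx)
  k <- circulation_kernel(circ, grid_dt)
  pool_after <- stats::filter(k$S * influx, k$F, method = "recursive")
  pool_start <- c(0, pool_after[-n])
  elim_old <- pool_start * (1 - k$F)
  elim_new <- influx * (1 - k$S)
  elim <- elim_old + elim_new
  lambda <- circ$c_frac * elim
  off <- ifelse(elim > 0,
                (elim_old * k$mt_old + elim_new * k$mt_new) / elim,
                grid_dt / 2)
  df <- data.frame(t0 = edges[-(n + 1L)],
                   mean_t = edges[-(n + 1L)] + off,
                   lambda = lambda)
  list(df = df, pool_end = as.numeric(pool_after[n]))
}

#' First-order colonization intensity from a primary-tumour trajectory
#'
#' Pushes the primary's per-generation disseminated cells through the
#' circulating pool and reports the expected number of colonizing cells per
#' bin of a uniform time grid, together with the mean colonization time
#' within each bin.  Cells enter circulation uniformly over their generation
#' step; after the trajectory ends the residual pool keeps resolving until
#' `horizon`.
#'
#' @param traj A `trajectory` from [ms_trajectory()] or [gdr_trajectory()].
#' @param circ A [circulation_params()] object.
#' @param grid_dt Reporting grid width in days (default 1).
#' @param horizon End of the reporting grid in days; defaults to the
#'   trajectory's end plus thirty circulation lifetimes.
#' @param excision_time If set, dissemination stops at this time (surgical
#'   removal of the primary); the residual circulating pool still resolves.
#'
#' @return A `colonization_intensity`: data frame with columns `t0` (bin
#'   start), `mean_t` (mean colonization time in the bin) and `lambda`
#'   (expected colonizing cells), with attributes `order`, `grid_dt`,
#'   `total_influx` and `pool_end`.
#' @export
first_order_intensity <- function(traj, circ, grid_dt = 1, horizon = NULL,
                                  excision_time = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(circ, "circulation_params"),
            grid_dt > 0)
  if (is.null(horizon)) horizon <- attr(traj, "t_end") + 30 * circ$T_env
  # uniform grid (chain_circulation assumes equal bins); horizon rounded down
  edges <- seq(0, by = grid_dt, length.out = floor(horizon / grid_dt) + 1L)
  cum <- cumulative_dissemination(traj, edges, cutoff = excision_time)
  influx <- diff(cum)
  res <- chain_circulation(influx, edges, circ, grid_dt)
  new_intensity(res$df, order = 1L, grid_dt = grid_dt, circ = circ,
                total_influx = cum[length(cum)], pool_end = res$pool_end)
}
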
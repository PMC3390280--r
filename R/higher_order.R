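# Expected dissemination (cells/bin) from all cohorts of a registry on a
# uniform grid.  Shedding follows the same rule as the primary: during a
# colony generation of start size x_n the colony sheds m * x_n^alpha
# (per_generation clock) or m * x_n^alpha * T_G_n/T_G0 (per_time), spread
# uniformly over the generation; a colony whose engine has stopped cycling
# sheds nothing.
registry_dissemination <- function(registry, edges, cfg) {
  grid_dt <- edges[2L] - edges[1L]
  mid <- edges[-length(edges)] + grid_dt / 2
  out <- numeric(length(mid))
  ch <- registry$cohorts
  for (g in names(registry$curves)) {
    sel <- ch$seed_gen == as.integer(g)
    if (!any(sel)) next
    cv <- registry$curves[[g]]
    tr <- cv$curve
    divisor <- if (cfg$dissemination_clock == "per_time")
      attr(tr, "T_G0") else tr$T_G
    r_k <- cfg$m * tr$cells^cfg$alpha_d / divisor
    rate_at <- stats::approxfun(c(tr$t_start, attr(tr, "t_end")),
                                c(r_k, 0), method = "constant",
                                yleft = 0, yright = 0, f = 0)
    ages <- outer(mid, ch$t_seed[sel], "-")
    rate <- matrix(rate_at(pmax(ages, -1) / cv$scale) / cv$scale,
                   nrow(ages), ncol(ages))
    rate[ages < 0] <- 0
    out <- out + as.numeric(rate %*% ch$count[sel]) * grid_dt
  }
  out
}

#' Higher-order colonization intensities (metastases from metastases)
#'
#' Recursion over metastatic orders: the cohorts of an order-`k` registry
#' shed cells with the same dissemination rule as the primary; the shed cells
#' pass through the circulating pool and colonize as order `k + 1`.  All
#' arithmetic is on expected values (fractional colonies).  Higher-order
#' colonies grow like the primary.
#'
#' @param registry An order-`k` `colony_registry` (usually order 1 from
#'   [build_colony_registry()]).
#' @param circ A [circulation_params()] object.
#' @param cfg The [generation_config()] supplying the dissemination rule.
#' @param max_order Highest metastatic order to compute (1 to 3).  With
#'   `max_order = 1` nothing is added and an empty list is returned.
#' @param grid_dt Grid width in days (default: spacing of the registry's
#'   seeds' grid, normally 1).
#'
#' @return A list of `colonization_intensity` objects for orders
#'   `registry$order + 1` up to `max_order`, each carrying its registry in
#'   attribute `registry`.
#' @export
higher_order_intensity <- function(registry, circ, cfg, max_order = 3,
                                   grid_dt = 1) {
  stopifnot(inherits(registry, "colony_registry"),
            inherits(circ, "circulation_params"))
  if (max_order < 1) stop("'max_order' must be at least 1")
  if (max_order > 3) stop("'max_order' above 3 is not supported")
  out <- list()
  cur <- registry
  while (cur$order < max_order) {
    edges <- seq(0, by = grid_dt,
                 length.out = floor(cur$horizon / grid_dt) + 1L)
    influx <- registry_dissemination(cur, edges, cfg)
    res <- chain_circulation(influx, edges, circ, grid_dt)
    intensity <- new_intensity(res$df, order = cur$order + 1L,
                               grid_dt = grid_dt, circ = circ,
                               total_influx = sum(influx),
                               pool_end = res$pool_end)
    reg_next <- build_colony_registry(intensity, "primary_like",
                                      cur$params, cur$config,
                                      traj = cur$traj, horizon = cur$horizon)
    attr(intensity, "registry") <- reg_next
    out[[length(out) + 1L]] <- intensity
    cur <- reg_next
  }
  out
}

#' Simulate the full expected-value metastatic cascade
#'
#' Front end tying the modules together: grows the primary with the
#' configured engine, pushes disseminated cells through circulation, builds
#' the first-order colony registry and, if requested, the higher-order
#' recursion.
#'
#' @param p A [gompertz_params()] object.
#' @param cfg A [generation_config()].
#' @param circ A [circulation_params()] object.
#' @param horizon Simulation horizon in days since tumour initiation.
#' @param grid_dt Reporting grid width in days.
#' @param max_order Highest metastatic order (1-3).
#' @param variant [growth_variant()] of the first-order colonies.
#' @param excision_time Optional time at which the primary is removed
#'   (dissemination stops; existing colonies keep growing).
#'
#' @return A `metastatic_cascade` object: list with the primary `trajectory`
#'   (`$traj`), per-order intensities (`$intensities`) and colony registries
#'   (`$registries`).
#' @examples
#' p <- gompertz_params(b = 7.3e10, mu = 0.00286)
#' cfg <- generation_config("MS", m = 2.5e-6, alpha_d = 1)
#' casc <- metastatic_cascade(p, cfg, circulation_params(), horizon = 1200)
#' colonies_above(casc$registries, threshold = 4.6e7, t = 1110)
#' @export
metastatic_cascade <- function(p, cfg, circ = circulation_params(),
                               horizon, grid_dt = 1, max_order = 1,
                               variant = "primary_like",
                               excision_time = NULL) {
  traj <- run_engine(p, cfg, horizon)
  int1 <- first_order_intensity(traj, circ, grid_dt = grid_dt,
                                horizon = horizon,
                                excision_time = excision_time)
  reg1 <- build_colony_registry(int1, variant, p, cfg, traj = traj,
                                horizon = horizon)
  intensities <- list(int1)
  registries <- list(reg1)
  if (max_order > 1) {
    hi <- higher_order_intensity(reg1, circ, cfg, max_order = max_order,
                                 grid_dt = grid_dt)
    for (h in hi) {
      intensities[[length(intensities) + 1L]] <- h
      registries[[length(registries) + 1L]] <- attr(h, "registry")
    }
  }
  structure(list(traj = traj, intensities = intensities,
                 registries = registries, params = p, config = cfg,
                 circ = circ, horizon = horizon, grid_dt = grid_dt,
                 variant = growth_variant(variant),
                 excision_time = excision_time),
            class = "metastatic_cascade")
}

#' @export
print.metastatic_cascade <- function(x, ...) {
  cat(sprintf("<metastatic_cascade> %s engine, horizon %.0f days, %d order(s)\n",
              x$config$engine, x$horizon, length(x$registries)))
  for (k in seq_along(x$intensities))
    cat(sprintf("  order %d: %.4g expected colonies\n",
                k, sum(x$intensities[[k]]$lambda)))
  invisible(x)
}

#' @export
summary.metastatic_cascade <- function(object, t = NULL,
                                       threshold = NULL, ...) {
  if (is.null(t)) t <- object$horizon
  print(object)
  cat(sprintf("  primary size at day %.0f: %.4g cells\n",
              t, size_at(object$traj, t)))
  cat(sprintf("  metastatic mass (order 1): %.4g cells\n",
              metastatic_mass(object$registries[[1L]], t)))
  if (!is.null(threshold))
    cat(sprintf("  colonies >= %.3g cells: %.4g\n", threshold,
                colonies_above(object$registries, threshold, t)))
  invisible(object)
}

#' @export
plot.metastatic_cascade <- function(x, ...) {
  tt <- seq(0, x$horizon, length.out = 200)
  prim <- size_at(x$traj, tt)
  mets <- metastatic_mass(x$registries[[1L]], tt)
  plot(tt, prim, type = "l", log = "y", xlab = "days since initiation",
       ylab = "cells", ylim = range(c(prim, pmax(mets, 1)), na.rm = TRUE), ...)
  graphics::lines(tt, pmax(mets, 1e-300), col = 2)
  graphics::legend("bottomright", c("primary", "metastatic mass"),
                   col = 1:2, lty = 1, bty = "n")
  invisible(x)
}
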
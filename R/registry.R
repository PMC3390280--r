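#' Growth variant of metastatic colonies
#'
#' Metastatic colonies restart their growth from a single cell.  By default
#' they grow exactly like the primary (`"primary_like"`).  Two reduced
#' variants inherit the state of the primary's generation at which the
#' founding cell was disseminated: `"gdr_inherited_d"` starts the GDR decay
#' schedule at that generation's doubling fraction (lower asymptotic colony
#' size), `"ms_inherited_TG"` starts with that generation's prolonged
#' generation time (same asymptote, slower growth — inherited ageing).
#'
#' @param kind One of `"primary_like"`, `"gdr_inherited_d"`,
#'   `"ms_inherited_TG"`.
#' @return The validated variant string (class `growth_variant`).
#' @export
growth_variant <- function(kind = c("primary_like", "gdr_inherited_d",
                                    "ms_inherited_TG")) {
  structure(match.arg(kind), class = "growth_variant")
}

#' Build a registry of metastatic colony cohorts
#'
#' Turns each bin of a colonization intensity into a cohort of expected
#' colonies seeded at the bin's mean colonization time, growing from one cell
#' under the chosen [growth_variant()].
#'
#' @param intensity A `colonization_intensity` from
#'   [first_order_intensity()] or [higher_order_intensity()].
#' @param variant A [growth_variant()] (or its string name).
#' @param p,cfg Growth law and engine configuration of the colonies
#'   (normally those of the primary).
#' @param traj The primary's `trajectory`; required for the inherited
#'   variants to map seed times to the primary's generation index, and reused
#'   as the colony growth curve when it starts from one cell.
#' @param horizon Maximum colony age (days) for which sizes are needed;
#'   defaults to the intensity's grid end.
#'
#' @return A `colony_registry`: list with `cohorts` (data frame `t_seed`,
#'   `count`, `seed_gen`), the variant, and an internal size table.
#' @export
build_colony_registry <- function(intensity, variant = "primary_like",
                                  p, cfg, traj = NULL, horizon = NULL) {
  stopifnot(inherits(intensity, "colonization_intensity"),
            inherits(p, "gompertz_params"),
            inherits(cfg, "generation_config"))
  variant <- growth_variant(variant)
  if (is.null(horizon))
    horizon <- max(intensity$t0) + attr(intensity, "grid_dt")
  keep <- intensity$lambda > 0
  cohorts <- data.frame(t_seed = intensity$mean_t[keep],
                        count = intensity$lambda[keep],
                        seed_gen = integer(sum(keep)))
  if (nrow(cohorts) == 0L) {
    # nothing colonized (e.g. m = 0)
  } else if (variant != "primary_like") {
    if (is.null(traj))
      stop("inherited growth variants need the primary trajectory 'traj'")
    idx <- findInterval(cohorts$t_seed, traj$t_start)
    idx[idx < 1L] <- 1L
    idx[idx > nrow(traj)] <- nrow(traj)
    cohorts$seed_gen <- traj$generation[idx]
  }
  structure(list(cohorts = cohorts, variant = variant, params = p,
                 config = cfg, traj = traj, horizon = horizon,
                 order = attr(intensity, "order"),
                 curves = registry_curves(variant, p, cfg, traj,
                                          unique(cohorts$seed_gen), horizon)),
            class = "colony_registry")
}

# One growth curve (a `trajectory` plus optional time-scale factor) per
# unique seed generation.
registry_curves <- function(variant, p, cfg, traj, gens, horizon) {
  base_cfg <- cfg
  base_cfg$m <- 0   # colony growth itself; shedding handled separately
  if (variant == "primary_like") {
    base <- if (!is.null(traj) && traj$cells[1L] == 1 &&
                attr(traj, "t_end") >= horizon) traj
            else run_engine(p, base_cfg, horizon)
    return(list(`0` = list(curve = base, scale = 1)))
  }
  if (variant == "ms_inherited_TG") {
    if (cfg$engine != "MS") stop("ms_inherited_TG requires the MS engine")
    base <- if (!is.null(traj) && traj$cells[1L] == 1) traj
            else run_engine(p, base_cfg, horizon)
    out <- lapply(gens, function(g) {
      x_seed <- base$cells[match(g, base$generation)]
      stretch <- log(p$b) / log(p$b / x_seed)
      list(curve = base, scale = stretch)
    })
    names(out) <- as.character(gens)
    return(out)
  }
  # gdr_inherited_d
  if (cfg$engine != "GDR") stop("gdr_inherited_d requires the GDR engine")
  out <- lapply(gens, function(g) {
    list(curve = gdr_trajectory(p, base_cfg, horizon, start_generation = g),
         scale = 1)
  })
  names(out) <- as.character(gens)
  out
}

run_engine <- function(p, cfg, horizon, ...) {
  if (cfg$engine == "MS") ms_trajectory(p, cfg, horizon, ...)
  else gdr_trajectory(p, cfg, horizon, ...)
}

#' @export
print.colony_registry <- function(x, ...) {
  cat(sprintf("<colony_registry> order %d, %d cohorts, variant %s\n",
              x$order, nrow(x$cohorts), unclass(x$variant)))
  if (nrow(x$cohorts))
    cat(sprintf("  expected colonies %.4g, seeds span days %.1f-%.1f\n",
                sum(x$cohorts$count),
                min(x$cohorts$t_seed), max(x$cohorts$t_seed)))
  invisible(x)
}

# Colony size of every cohort at absolute time t (vector over cohorts).
registry_sizes <- function(registry, t) {
  ch <- registry$cohorts
  out <- numeric(nrow(ch))
  age <- t - ch$t_seed
  alive <- age >= 0
  for (g in names(registry$curves)) {
    sel <- alive & ch$seed_gen == as.integer(g)
    if (!any(sel)) next
    cv <- registry$curves[[g]]
    out[sel] <- size_at(cv$curve, age[sel] / cv$scale)
  }
  out
}

#' Expected number of colonies above a size threshold
#'
#' Sums, over the cohorts of one or several registries, the expected colony
#' counts whose size at time `t` has reached `threshold` cells.
#'
#' @param registry A `colony_registry` or a list of them (e.g. one per
#'   metastatic order).
#' @param threshold Size threshold in cells (>= 1).
#' @param t Evaluation time in days since tumour initiation (vectorised).
#' @return Expected counts, one per `t`.
#' @export
colonies_above <- function(registry, threshold, t) {
  stopifnot(threshold >= 1)
  regs <- if (inherits(registry, "colony_registry")) list(registry)
          else registry
  vapply(t, function(tt) {
    sum(vapply(regs, function(r) {
      sz <- registry_sizes(r, tt)
      sum(r$cohorts$count[sz >= threshold])
    }, numeric(1)))
  }, numeric(1))
}

#' Total metastatic cell mass
#'
#' Expected total number of metastatic cells at time `t`: the cohort-weighted
#' sum of colony sizes.
#'
#' @inheritParams colonies_above
#' @return Cells, one value per `t`.
#' @export
metastatic_mass <- function(registry, t) {
  regs <- if (inherits(registry, "colony_registry")) list(registry)
          else registry
  vapply(t, function(tt) {
    sum(vapply(regs, function(r) {
      sum(r$cohorts$count * registry_sizes(r, tt))
    }, numeric(1)))
  }, numeric(1))
}

#' Time at which metastatic mass first equals the primary tumour
#'
#' Scans the reporting grid for the first time the total first-order
#' metastatic cell mass reaches the primary's size, then refines the crossing
#' by bisection on the interpolated curves.
#'
#' @param registry A `colony_registry` (typically first order).
#' @param traj The primary `trajectory`.
#' @param grid_dt Scan step in days.
#' @param horizon Scan end; defaults to the registry horizon.
#' @return Crossing time in days since initiation, or `NA` if never reached.
#' @export
mass_parity_time <- function(registry, traj, grid_dt = 5, horizon = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(horizon)) {
    horizon <- if (inherits(registry, "colony_registry")) registry$horizon
               else min(vapply(registry, `[[`, numeric(1), "horizon"))
  }
  tt <- seq(0, horizon, by = grid_dt)
  gap <- function(t) metastatic_mass(registry, t) - size_at(traj, t)
  gg <- metastatic_mass(registry, tt) - size_at(traj, tt)
  i <- which(gg >= 0)[1L]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(tt[1L])
  stats::uniroot(gap, c(tt[i - 1L], tt[i]), tol = 1e-3)$root
}
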
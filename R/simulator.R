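#' Simulation configuration
#'
#' @param dt forward-Euler time step in days (0.5 resolves the sampled
#'   parameter range at 1 mm spacing).
#' @param snapshot_times times (days since emergence) at which to return the
#'   density; taken at the nearest completed step (difference <= dt/2).
#' @param stability_check refuse to run when \code{dt} exceeds the explicit
#'   stability bound of the diffusion stencil.
#' @param clamp clip densities to [0, 1] after each step, removing the
#'   small undershoots and overshoots of the explicit anisotropic stencil
#'   near steep fronts (the clipped mass is reported). Turn off to obtain
#'   the raw conservative scheme, whose total mass with \code{rho = 0} is
#'   constant to round-off.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(dt = 0.5, snapshot_times = numeric(0),
                              stability_check = TRUE, clamp = TRUE) {
  if (dt <= 0) stop("dt must be positive")
  snapshot_times <- as.numeric(snapshot_times)
  if (is.unsorted(snapshot_times)) stop("snapshot_times must be non-decreasing")
  structure(list(dt = dt, snapshot_times = snapshot_times,
                 stability_check = stability_check, clamp = clamp),
            class = "simulation_config")
}

#' Place a tumor seed in white matter
#'
#' Draws a seed center uniformly among white-matter voxels whose full
#' 3x3x3 neighborhood (3x3 in 2D mode) lies inside the brain domain, and
#' sets the density to 1 on that neighborhood.
#'
#' @param brain a \code{\link{brain_map}} with non-empty white matter.
#' @param seed integer RNG seed; equal seeds give identical placements.
#' @return list with \code{field} (a \code{\link{density_field}} at t = 0)
#'   and \code{center} (voxel index triple of the seed center).
#' @export
place_seed <- function(brain, seed = 0) {
  eligible <- eligible_seed_centers(brain)
  if (nrow(eligible) == 0)
    stop("no white-matter voxel has a full neighborhood inside the brain domain")
  pick <- with_seed(seed, sample.int(nrow(eligible), 1))
  center <- eligible[pick, ]
  list(field = seed_field(brain, center), center = center)
}

# voxel index triples (matrix) of white voxels whose neighborhood is in-domain
eligible_seed_centers <- function(brain) {
  dims <- brain$dim
  dom <- brain_domain(brain)
  idx <- which(brain$labels == LABEL_WHITE, arr.ind = TRUE)
  if (nrow(idx) == 0) return(idx)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[apply(off, 1, function(o) all(dims[o != 0] > 1)), , drop = FALSE]
  ok <- rep(TRUE, nrow(idx))
  for (r in seq_len(nrow(off))) {
    nb <- sweep(idx, 2, off[r, ], "+")
    inside <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    good <- inside
    good[inside] <- dom[nb[inside, , drop = FALSE]]
    ok <- ok & good
  }
  idx[ok, , drop = FALSE]
}

seed_field <- function(brain, center) {
  dims <- brain$dim
  v <- array(0, dim = dims)
  rng <- lapply(1:3, function(i) {
    if (dims[i] == 1) 1L
    else max(1L, center[i] - 1L):min(dims[i], center[i] + 1L)
  })
  v[rng[[1]], rng[[2]], rng[[3]]] <- 1
  density_field(v, spacing = brain$spacing, time = 0)
}

#' Explicit-Euler stability limit of the diffusion stencil
#'
#' Conservative bound \code{dt <= 1 / (2 L)} with \code{L} the maximum over
#' voxels of \code{sum_i Dii / h_i^2 + sum_{i != j} |Dij| / (h_i h_j)},
#' tensor entries converted to mm^2/day. A zero field returns \code{Inf}.
#'
#' @param tensor a \code{\link{tensor_field}} in mm^2/year.
#' @param spacing voxel spacing in mm (defaults to the field's).
#' @return maximum stable time step in days.
#' @export
stability_limit <- function(tensor, spacing = tensor$spacing) {
  spacing <- rep_len(as.numeric(spacing), 3)
  L <- rd_stability_denominator_cpp(tensor$components / DAYS_PER_YEAR,
                                    spacing, tensor$dim)
  if (L <= 0) Inf else 1 / (2 * L)
}

#' Simulate anisotropic Fisher-KPP tumor growth
#'
#' Advances \code{dc/dt = div(D grad c) + rho c (1 - c)} by forward Euler
#' with a conservative flux-form discretization: face fluxes between voxel
#' pairs use face-averaged tensor entries (mixed-term gradients are
#' corner-averaged first differences), and any face touching a voxel outside
#' the brain domain carries zero flux, which implements the no-flux Neumann
#' boundary without ghost cells. Grids with a singleton dimension run in 2D
#' mode with identical properties.
#'
#' @param c0 initial \code{\link{density_field}} (time 0).
#' @param tensor tumor \code{\link{tensor_field}} in mm^2/year.
#' @param rho proliferation rate in 1/year.
#' @param brain a \code{\link{brain_map}} on the same grid.
#' @param config a \code{\link{simulation_config}} with snapshot times.
#' @return list of \code{\link{density_field}} snapshots, one per requested
#'   time, with attribute \code{"clipped_mass"} (total mass removed by
#'   [0, 1] clipping when \code{clamp} is on).
#' @export
simulate_growth <- function(c0, tensor, rho, brain,
                            config = simulation_config()) {
  check_same_grid(c0, brain, "density and brain map")
  check_same_grid(tensor, brain, "tensor and brain map")
  if (length(config$snapshot_times) == 0) stop("no snapshot_times requested")
  D_day <- tensor$components / DAYS_PER_YEAR
  if (config$stability_check) {
    bound <- stability_limit(tensor)
    if (config$dt > bound)
      stop(sprintf("dt = %g d violates the stability bound %.4g d", config$dt,
                   bound))
  }
  # half-up rounding so that shifting all times by a multiple of dt shifts
  # every snapshot by the same number of steps (round() ties-to-even breaks
  # this)
  steps <- as.integer(floor(config$snapshot_times / config$dt + 0.5))
  dom <- brain_domain(brain)
  res <- rd_simulate_cpp(as.vector(c0$values) * as.vector(dom), D_day,
                         as.integer(dom), brain$dim, brain$spacing,
                         config$dt, rho / DAYS_PER_YEAR, steps,
                         config$clamp)
  out <- lapply(seq_along(steps), function(i) {
    vals <- array(res$snapshots[, i], dim = brain$dim)
    if (config$clamp)
      density_field(vals, spacing = brain$spacing,
                    time = steps[i] * config$dt)
    else  # raw conservative scheme: undershoots are kept, skip the band check
      structure(list(values = vals, spacing = brain$spacing,
                     time = steps[i] * config$dt, dim = brain$dim),
                class = "density_field")
  })
  attr(out, "clipped_mass") <- res$clipped_mass
  out
}
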
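#' Growth-parameter estimate
#'
#' Holds an estimated infiltration length and front speed together with the
#' diffusivity and proliferation rate they imply, and the method that
#' produced them.
#'
#' @param lambda estimated infiltration length, mm.
#' @param v estimated front speed, mm/year.
#' @param method \code{"gridsearch"} or \code{"network"}.
#' @param details optional provenance (score surface, candidate grids, ...).
#' @return object of class \code{glioma_estimate}.
#' @export
glioma_estimate <- function(lambda, v, method = c("gridsearch", "network"),
                            details = list()) {
  method <- match.arg(method)
  rates <- derive_rates(lambda, v)
  structure(list(lambda = lambda, v = v, dwhite = rates$dwhite,
                 rho = rates$rho, method = method, details = details),
            class = "glioma_estimate")
}

#' @export
print.glioma_estimate <- function(x, ...) {
  cat(sprintf(
    "Glioma growth estimate (%s):\n  lambda = %.3f mm, v = %.2f mm/yr\n  dwhite = %.2f mm^2/yr, rho = %.2f /yr\n",
    x$method, x$lambda, x$v, x$dwhite, x$rho))
  invisible(x)
}

#' @export
coef.glioma_estimate <- function(object, ...) {
  c(lambda = object$lambda, v = object$v, dwhite = object$dwhite,
    rho = object$rho)
}

#' @export
summary.glioma_estimate <- function(object, ...) {
  print(object)
  if (!is.null(object$details$score))
    cat("  best contour-mismatch score: ",
        signif(object$details$score, 5), " mm (summed ASSD)\n", sep = "")
  invisible(object)
}

#' Forecast tumor growth from an estimate
#'
#' @param object a \code{\link{glioma_estimate}}.
#' @param c_t2 (post-processed) density field at the second imaging time.
#' @param unit_tensor unit tumor tensor of the subject.
#' @param brain the subject's brain map.
#' @param horizons forecast horizons in days after t2.
#' @param config a \code{\link{simulation_config}}.
#' @param ... unused.
#' @return list of \code{\link{density_field}}s, one per horizon.
#' @export
predict.glioma_estimate <- function(object, c_t2, unit_tensor, brain,
                                    horizons = c(90, 180),
                                    config = simulation_config(), ...) {
  forecast_density(c_t2, object$dwhite, object$rho, unit_tensor, brain,
                   horizons = horizons, config = config)
}

#' Brute-force grid-search estimation of growth parameters
#'
#' Independent inverse-problem oracle usable when the tumor seed is known
#' (synthetic records): every candidate (lambda, v) pair is simulated from
#' the seed over the rescaled unit tensor, its imaging contours are
#' extracted at the observation times and thresholds, and the candidate
#' minimizing the summed average symmetric surface distance to the three
#' observed contours is returned. Ties break toward smaller lambda, then
#' smaller v.
#'
#' @param gamma1 observed core region at t2 (\code{\link{threshold_region}}).
#' @param gamma2 observed edema region at t2.
#' @param gamma3 observed edema region at t1.
#' @param t1 first imaging time, days since emergence.
#' @param dt2 interval between t1 and t2, days.
#' @param brain the subject's \code{\link{brain_map}}.
#' @param unit_tensor unit tumor \code{\link{tensor_field}}.
#' @param seed_center voxel index triple of the known seed.
#' @param lambda_grid,v_grid candidate values (non-empty).
#' @param config a \code{\link{simulation_config}}.
#' @return a \code{\link{glioma_estimate}} with the score surface in
#'   \code{details}.
#' @export
gridsearch_estimate <- function(gamma1, gamma2, gamma3, t1, dt2, brain,
                                unit_tensor, seed_center,
                                lambda_grid, v_grid,
                                config = simulation_config()) {
  if (length(lambda_grid) == 0 || length(v_grid) == 0)
    stop("empty candidate grid")
  for (g in list(gamma1, gamma2, gamma3))
    if (!any(g$mask)) stop("observed contour is empty")
  obs <- list(extract_surface(gamma1), extract_surface(gamma2),
              extract_surface(gamma3))
  c0 <- seed_field(brain, seed_center)
  t2 <- t1 + dt2
  lambda_grid <- sort(lambda_grid)
  v_grid <- sort(v_grid)
  scores <- matrix(Inf, length(lambda_grid), length(v_grid),
                   dimnames = list(signif(lambda_grid, 6), signif(v_grid, 6)))
  best <- list(score = Inf, lambda = NA_real_, v = NA_real_)
  for (i in seq_along(lambda_grid)) for (j in seq_along(v_grid)) {
    pars <- derive_rates(lambda_grid[i], v_grid[j])
    tensor <- scale_tumor_tensor(unit_tensor, pars$dwhite)
    cfg <- simulation_config(dt = config$dt, snapshot_times = c(t1, t2),
                             stability_check = config$stability_check,
                             clamp = config$clamp)
    snaps <- simulate_growth(c0, tensor, pars$rho, brain, cfg)
    sims <- list(threshold_region(snaps[[2]], gamma1$threshold),
                 threshold_region(snaps[[2]], gamma2$threshold),
                 threshold_region(snaps[[1]], gamma3$threshold))
    sc <- 0
    for (k in 1:3) {
      if (!any(sims[[k]]$mask)) { sc <- Inf; break }
      sc <- sc + assd(extract_surface(sims[[k]]), obs[[k]])
    }
    scores[i, j] <- sc
    if (sc < best$score)
      best <- list(score = sc, lambda = lambda_grid[i], v = v_grid[j])
  }
  if (!is.finite(best$score))
    stop("no candidate produced non-empty contours at the observation times")
  glioma_estimate(best$lambda, best$v, method = "gridsearch",
                  details = list(score = best$score, scores = scores,
                                 lambda_grid = lambda_grid, v_grid = v_grid))
}
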
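#' Post-process an estimated density field
#'
#' Cleans a reconstructed density before it seeds a forecast, in order:
#' (1) densities of non-brain voxels (CSF and background) are set to 0;
#' (2) values are clipped to [0, 1]; (3) voxels outside the largest
#' 26-connected region with density above 1e-6 are set to 0, removing the
#' sporadic far-from-tumor local maxima that would otherwise grow into
#' spurious foci. Idempotent; an all-zero result raises a warning, not an
#' error.
#'
#' @param c_est estimated \code{\link{density_field}} (or a bare list with
#'   \code{values}/\code{spacing}/\code{time}, for raw network output).
#' @param brain the subject's \code{\link{brain_map}}.
#' @return a post-processed \code{\link{density_field}}.
#' @export
postprocess_density <- function(c_est, brain) {
  v <- c_est$values
  stopifnot(identical(dim(v), as.integer(brain$dim)) ||
              identical(as.integer(dim(v)), as.integer(brain$dim)))
  v[!brain_domain(brain)] <- 0
  v[v < 0] <- 0
  v[v > 1] <- 1
  keep <- largest_component_cpp(as.vector(v > 1e-6), brain$dim, 26L)
  v[!array(keep, dim = dim(v))] <- 0
  if (all(v == 0)) warning("post-processed density field is identically zero")
  density_field(v, spacing = brain$spacing, time = c_est$time)
}

#' Forecast a density field forward in time
#'
#' Scales the unit tumor tensor by the (estimated) white-matter diffusivity
#' and integrates the growth model from the given state for each horizon.
#'
#' @param c_t2 starting \code{\link{density_field}} (post-processed when it
#'   comes from a network).
#' @param dwhite white-matter diffusivity, mm^2/year.
#' @param rho proliferation rate, 1/year.
#' @param unit_tensor unit tumor \code{\link{tensor_field}}.
#' @param brain the subject's \code{\link{brain_map}}.
#' @param horizons days after the starting time (default 90 and 180).
#' @param config a \code{\link{simulation_config}}.
#' @return list of \code{\link{density_field}}s, one per horizon, with
#'   absolute time stamps.
#' @export
forecast_density <- function(c_t2, dwhite, rho, unit_tensor, brain,
                             horizons = c(90, 180),
                             config = simulation_config()) {
  if (dwhite <= 0 || rho <= 0) stop("parameters must be positive")
  tensor <- scale_tumor_tensor(unit_tensor, dwhite)
  cfg <- simulation_config(dt = config$dt, snapshot_times = sort(horizons),
                           stability_check = config$stability_check,
                           clamp = config$clamp)
  snaps <- simulate_growth(c_t2, tensor, rho, brain, cfg)
  for (i in seq_along(snaps)) snaps[[i]]$time <- c_t2$time + snaps[[i]]$time
  snaps
}

metric_row <- function(true_f, est_f, thresholds) {
  surf <- function(f, thr) {
    reg <- threshold_region(f, thr)
    if (!any(reg$mask)) return(NULL)
    extract_surface(reg)
  }
  out <- list(time = true_f$time, mae = masked_mae(true_f, est_f))
  for (k in seq_along(thresholds)) {
    a <- surf(true_f, thresholds[k])
    b <- surf(est_f, thresholds[k])
    lab <- paste0("c", k)
    if (is.null(a) || is.null(b)) {
      out[[paste0("hausdorff_", lab)]] <- NA_real_
      out[[paste0("assd_", lab)]] <- NA_real_
    } else {
      d <- set_distances_cpp(unclass(a), unclass(b))
      out[[paste0("hausdorff_", lab)]] <- d$hausdorff
      out[[paste0("assd_", lab)]] <- d$assd
    }
  }
  as.data.frame(out)
}

#' Evaluate an estimated tumor state and parameters against the truth
#'
#' Forecasts from the estimated t2 density with the estimated parameters to
#' t3 and t4, then reports the masked MAE and the Hausdorff and average
#' symmetric surface distances at both imaging thresholds for each of t2,
#' t3 and t4. A time/threshold cell whose true or estimated contour is
#' empty is reported as NA rather than an error. Parameter relative errors
#' are included when an estimate is supplied.
#'
#' @param record the true \code{tumor_record} (snapshots at t2-t4).
#' @param est_t2 estimated density at t2 (post-processed).
#' @param est_params a \code{\link{glioma_estimate}}, or NULL to forecast
#'   with the true parameters.
#' @param unit_tensor the subject's unit tensor.
#' @param brain the subject's brain map.
#' @param thresholds imaging thresholds (core, edema).
#' @param config a \code{\link{simulation_config}}.
#' @return list of class \code{forecast_report}: \code{metrics} (data.frame
#'   with one row per time point), \code{parameter_errors} (relative
#'   errors), \code{forecasts} (the estimated fields at t3, t4).
#' @export
evaluate_forecast <- function(record, est_t2, est_params, unit_tensor, brain,
                              thresholds = c(0.80, 0.16),
                              config = simulation_config()) {
  p <- record$parameters
  dwhite <- if (is.null(est_params)) p$dwhite else est_params$dwhite
  rho <- if (is.null(est_params)) p$rho else est_params$rho
  fc <- forecast_density(est_t2, dwhite, rho, unit_tensor, brain,
                         horizons = c(record$times[["t3"]] - record$times[["t2"]],
                                      record$times[["t4"]] - record$times[["t2"]]),
                         config = config)
  est_fields <- c(list(est_t2), fc)
  true_fields <- record$snapshots[2:4]
  metrics <- do.call(rbind, Map(function(tf, ef) metric_row(tf, ef, thresholds),
                                true_fields, est_fields))
  perr <- NULL
  if (!is.null(est_params))
    perr <- c(lambda = relative_error(p$lambda, est_params$lambda),
              v = relative_error(p$v, est_params$v),
              dwhite = relative_error(p$dwhite, est_params$dwhite),
              rho = relative_error(p$rho, est_params$rho))
  structure(list(metrics = metrics, parameter_errors = perr, forecasts = fc),
            class = "forecast_report")
}

#' @export
print.forecast_report <- function(x, ...) {
  cat("Forecast evaluation:\n")
  print(x$metrics, row.names = FALSE)
  if (!is.null(x$parameter_errors)) {
    cat("Parameter relative errors:\n")
    print(round(x$parameter_errors, 4))
  }
  invisible(x)
}

#' Median metrics over a set of forecast reports
#'
#' Medians are taken per metric and time point, excluding undefined (NA)
#' cells; the count of undefined cells is reported alongside.
#'
#' @param reports list of \code{\link{evaluate_forecast}} results.
#' @return data.frame of medians with an \code{n_undefined} column.
#' @export
summarize_forecasts <- function(reports) {
  all_rows <- do.call(rbind, lapply(reports, `[[`, "metrics"))
  cols <- setdiff(names(all_rows), "time")
  do.call(rbind, lapply(split(all_rows, all_rows$time), function(df) {
    out <- data.frame(time = df$time[1])
    for (cl in cols) out[[paste0("median_", cl)]] <- median(df[[cl]], na.rm = TRUE)
    out$n_undefined <- sum(is.na(df[cols]))
    out
  }))
}

#' Threshold sensitivity analysis of parameter estimation
#'
#' Re-runs an estimator on the test records after perturbing the imaging
#' thresholds used to build its input contours (the evaluation targets are
#' unchanged) and reports, per perturbation combination, the median
#' relative errors and concordance coefficients of the estimated
#' parameters — quantifying robustness to uncertainty in the detectability
#' thresholds.
#'
#' @param dataset a \code{\link{build_dataset}} result.
#' @param estimator function(record, thresholds) returning a
#'   \code{\link{glioma_estimate}}, fed perturbed-threshold contours.
#' @param perturbations fractional changes applied to (c1, c2); default all
#'   four combinations of -10\% and +10\%.
#' @param record_idx records to evaluate (default the test split).
#' @return data.frame with one row per perturbation combination.
#' @export
sensitivity_analysis <- function(dataset, estimator,
                                 perturbations = expand.grid(
                                   p1 = c(-0.10, 0.10), p2 = c(-0.10, 0.10)),
                                 record_idx = dataset$test_idx) {
  base_thr <- dataset$thresholds
  rows <- lapply(seq_len(nrow(perturbations)), function(r) {
    p1 <- perturbations$p1[r]; p2 <- perturbations$p2[r]
    thr <- c(base_thr[1] * (1 + p1), base_thr[2] * (1 + p2))
    if (any(thr <= 0 | thr >= 1))
      stop("perturbation drives a threshold outside (0, 1): ",
           paste(signif(thr, 4), collapse = ", "))
    true_l <- numeric(0); true_v <- numeric(0)
    est_l <- numeric(0); est_v <- numeric(0)
    for (i in record_idx) {
      rec <- dataset$records[[i]]
      rec$regions <- list(
        core_t2 = threshold_region(rec$snapshots[[2]], thr[1]),
        edema_t2 = threshold_region(rec$snapshots[[2]], thr[2]),
        edema_t1 = threshold_region(rec$snapshots[[1]], thr[2]))
      est <- estimator(rec, thr)
      true_l <- c(true_l, rec$parameters$lambda)
      true_v <- c(true_v, rec$parameters$v)
      est_l <- c(est_l, est$lambda)
      est_v <- c(est_v, est$v)
    }
    tr <- derive_rates(true_l, true_v); er <- derive_rates(est_l, est_v)
    data.frame(
      p_c1 = p1, p_c2 = p2,
      mre_lambda = median(relative_error(true_l, est_l)),
      mre_v = median(relative_error(true_v, est_v)),
      mre_dwhite = median(relative_error(tr$dwhite, er$dwhite)),
      mre_rho = median(relative_error(tr$rho, er$rho)),
      ccc_lambda = concordance_ccc(true_l, est_l),
      ccc_v = concordance_ccc(true_v, est_v))
  })
  do.call(rbind, rows)
}
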
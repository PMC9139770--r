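#' Sampling ranges for tumor growth parameters
#'
#' Uniform ranges from which each synthetic tumor draws its infiltration
#' length, front speed and first two imaging intervals: lambda in
#' [0.5, 2.0] mm and v in [28.28, 48.99] mm/year (continuous), dt1 and dt2
#' in [90, 180] days (integer, both endpoints included). The third and
#' fourth intervals are fixed at 90 days for forecasting verification.
#'
#' @param lambda,v,dt1,dt2 length-2 numeric ranges (min, max).
#' @return list of class \code{sampling_ranges}.
#' @export
sampling_ranges <- function(lambda = c(0.5, 2.0), v = c(28.28, 48.99),
                            dt1 = c(90L, 180L), dt2 = c(90L, 180L)) {
  for (r in list(lambda, v, dt1, dt2))
    if (length(r) != 2 || r[1] >= r[2]) stop("each range needs min < max")
  structure(list(lambda = as.numeric(lambda), v = as.numeric(v),
                 dt1 = as.integer(dt1), dt2 = as.integer(dt2)),
            class = "sampling_ranges")
}

#' Derive diffusivity and proliferation rate from wave parameters
#'
#' Inverts the asymptotic traveling-wave relations of the Fisher-KPP model,
#' \code{v = 2 sqrt(d rho)} and \code{lambda = sqrt(d / rho)}:
#' \code{dwhite = lambda * v / 2} (mm^2/year) and
#' \code{rho = v / (2 * lambda)} (1/year).
#'
#' @param lambda infiltration length, mm.
#' @param v front propagation speed, mm/year.
#' @return named list with \code{dwhite} and \code{rho}.
#' @export
derive_rates <- function(lambda, v) {
  if (any(lambda <= 0) || any(v <= 0)) stop("lambda and v must be positive")
  list(dwhite = lambda * v / 2, rho = v / (2 * lambda))
}

#' Sample a set of tumor growth parameters
#'
#' Draws lambda and v uniform-continuous and dt1, dt2 uniform-integer
#' (inclusive) from the configured ranges, then derives \code{dwhite} and
#' \code{rho}. Sampling the (lambda, v) box rather than (dwhite, rho)
#' directly avoids tumors too small to show a visible core or so aggressive
#' they fill the brain.
#'
#' @param ranges a \code{\link{sampling_ranges}}.
#' @param seed integer RNG seed; draws are deterministic per seed.
#' @return list of class \code{growth_parameters} with fields
#'   \code{lambda}, \code{v}, \code{dwhite}, \code{rho}, \code{dt1},
#'   \code{dt2}, \code{dt3}, \code{dt4} and times \code{t1}..\code{t4}.
#' @export
sample_parameters <- function(ranges = sampling_ranges(), seed = 0) {
  with_seed(seed, {
    lambda <- runif(1, ranges$lambda[1], ranges$lambda[2])
    v <- runif(1, ranges$v[1], ranges$v[2])
    dt1 <- sample(ranges$dt1[1]:ranges$dt1[2], 1)
    dt2 <- sample(ranges$dt2[1]:ranges$dt2[2], 1)
    growth_parameters(lambda, v, dt1, dt2)
  })
}

#' Assemble growth parameters from wave quantities and imaging intervals
#' @param lambda infiltration length, mm.
#' @param v front speed, mm/year.
#' @param dt1,dt2 first two imaging intervals, days.
#' @param dt3,dt4 verification intervals, days (fixed 90 by default).
#' @return list of class \code{growth_parameters}.
#' @export
growth_parameters <- function(lambda, v, dt1, dt2, dt3 = 90, dt4 = 90) {
  rates <- derive_rates(lambda, v)
  dts <- c(dt1, dt2, dt3, dt4)
  times <- cumsum(dts)
  structure(list(lambda = lambda, v = v, dwhite = rates$dwhite,
                 rho = rates$rho, dt1 = dt1, dt2 = dt2, dt3 = dt3, dt4 = dt4,
                 t1 = times[1], t2 = times[2], t3 = times[3], t4 = times[4]),
            class = "growth_parameters")
}

#' @export
print.growth_parameters <- function(x, ...) {
  cat(sprintf(
    "Growth parameters: lambda = %.3f mm, v = %.2f mm/yr (d = %.2f mm^2/yr, rho = %.2f /yr)\n",
    x$lambda, x$v, x$dwhite, x$rho))
  cat(sprintf("  imaging times t1-t4: %g, %g, %g, %g d\n",
              x$t1, x$t2, x$t3, x$t4))
  invisible(x)
}

#' Synthesize one tumor record
#'
#' Places a seed, samples growth parameters, scales the unit tumor tensor
#' by the sampled \code{dwhite}, and integrates the growth model from
#' emergence through t4, storing density snapshots at the four imaging
#' times. Draws whose visible core (c >= 0.80 region at t2) is empty, or
#' whose c > 0.01 region covers more than 90% of the brain domain at t2,
#' are rejected and resampled (at most \code{max_attempts} times, with the
#' rejection count recorded).
#'
#' @param brain a \code{\link{brain_map}}.
#' @param unit_tensor unit tumor \code{\link{tensor_field}} (dwhite = 1).
#' @param ranges a \code{\link{sampling_ranges}}.
#' @param seed integer RNG seed for this record.
#' @param config a \code{\link{simulation_config}} (snapshot times are set
#'   internally from the sampled imaging schedule).
#' @param subject_id identifier stored in the record.
#' @param max_attempts rejection-sampling budget.
#' @return list of class \code{tumor_record}: \code{subject_id},
#'   \code{seed_center}, \code{parameters}, \code{times},
#'   \code{snapshots} (four \code{\link{density_field}}s),
#'   \code{provenance} (seed, dt, rejection count).
#' @export
synthesize_tumor <- function(brain, unit_tensor, ranges = sampling_ranges(),
                             seed = 0, config = simulation_config(),
                             subject_id = "subject", max_attempts = 50) {
  placement <- place_seed(brain, seed = seed)
  dom_size <- sum(brain_domain(brain))
  for (attempt in seq_len(max_attempts)) {
    pars <- sample_parameters(ranges, seed = seed + 7919L * (attempt - 1L))
    cfg <- simulation_config(dt = config$dt,
                             snapshot_times = c(pars$t1, pars$t2, pars$t3,
                                                pars$t4),
                             stability_check = config$stability_check,
                             clamp = config$clamp)
    tensor <- scale_tumor_tensor(unit_tensor, pars$dwhite)
    snaps <- simulate_growth(placement$field, tensor, pars$rho, brain, cfg)
    core_t2 <- sum(snaps[[2]]$values >= 0.80)
    fill_t2 <- sum(snaps[[2]]$values > 0.01) / dom_size
    if (core_t2 > 0 && fill_t2 <= 0.90) {
      # snapshot times as realized on the solver step grid; the 90-day
      # verification gaps stay exact whenever dt divides 90
      actual <- vapply(snaps, `[[`, numeric(1), "time")
      return(structure(list(
        subject_id = subject_id,
        seed_center = placement$center,
        parameters = pars,
        times = c(t1 = actual[1], t2 = actual[2], t3 = actual[3],
                  t4 = actual[4]),
        snapshots = snaps,
        provenance = list(seed = seed, dt = cfg$dt,
                          rejections = attempt - 1L)),
        class = "tumor_record"))
    }
  }
  stop("parameter ranges incompatible with geometry: ", max_attempts,
       " consecutive draws rejected (empty core or > 90% brain fill at t2)")
}

#' @export
print.tumor_record <- function(x, ...) {
  cat("Tumor record [", x$subject_id, "]: seed at (",
      paste(x$seed_center, collapse = ", "), "), t1-t4 = ",
      paste(x$times, collapse = ", "), " d, ", x$provenance$rejections,
      " rejected draws\n", sep = "")
  print(x$parameters)
  invisible(x)
}

#' Build a synthetic tumor dataset with a subject-wise split
#'
#' Generates \code{tumors_per_subject} records for each subject and splits
#' them train/test on a subject basis: all records of the last subject form
#' the test set (an 83/17 split for 6 subjects). Per-record RNG seeds are
#' derived from the master seed so each record is independently
#' reproducible. The bundle stores, per record, the binary regions at the
#' core/edema thresholds alongside the density snapshots, plus the
#' standardization constants of the target parameters.
#'
#' @param subjects named list of subjects, each a list with elements
#'   \code{map} (\code{\link{brain_map}}) and \code{unit_tensor}
#'   (\code{\link{tensor_field}}); at least 2 for a split.
#' @param tumors_per_subject records per subject.
#' @param ranges a \code{\link{sampling_ranges}}.
#' @param seed master RNG seed.
#' @param config a \code{\link{simulation_config}}.
#' @param thresholds imaging thresholds (core, edema).
#' @param out_path optional directory; when given, a JSON manifest and a CSV
#'   parameter table are written there.
#' @return list of class \code{tumor_dataset}: \code{records},
#'   \code{train_idx}, \code{test_idx}, \code{ranges},
#'   \code{standardization}, \code{thresholds}, \code{manifest}.
#' @export
build_dataset <- function(subjects, tumors_per_subject,
                          ranges = sampling_ranges(), seed = 0,
                          config = simulation_config(),
                          thresholds = c(0.80, 0.16), out_path = NULL) {
  if (length(subjects) < 2) stop("need at least 2 subjects for a split")
  if (is.null(names(subjects)))
    names(subjects) <- sprintf("subject%02d", seq_along(subjects))
  n_total <- length(subjects) * tumors_per_subject
  record_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1,
                                             n_total))
  records <- vector("list", n_total)
  k <- 0
  for (s in seq_along(subjects)) {
    subj <- subjects[[s]]
    for (j in seq_len(tumors_per_subject)) {
      k <- k + 1
      rec <- synthesize_tumor(subj$map, subj$unit_tensor, ranges,
                              seed = record_seeds[k], config = config,
                              subject_id = names(subjects)[s])
      rec$subject_index <- s
      rec$regions <- list(
        core_t2 = threshold_region(rec$snapshots[[2]], thresholds[1]),
        edema_t2 = threshold_region(rec$snapshots[[2]], thresholds[2]),
        edema_t1 = threshold_region(rec$snapshots[[1]], thresholds[2]))
      records[[k]] <- rec
    }
  }
  subject_of <- rep(seq_along(subjects), each = tumors_per_subject)
  test_idx <- which(subject_of == length(subjects))
  manifest <- list(
    seed = seed, tumors_per_subject = tumors_per_subject,
    subjects = names(subjects), record_seeds = record_seeds,
    thresholds = thresholds, dt = config$dt,
    ranges = unclass(ranges))
  ds <- structure(list(
    records = records,
    train_idx = setdiff(seq_len(n_total), test_idx),
    test_idx = test_idx,
    ranges = ranges,
    standardization = target_standardization(ranges),
    thresholds = thresholds,
    manifest = manifest), class = "tumor_dataset")
  if (!is.null(out_path)) {
    dir.create(out_path, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out_path, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(dataset_parameter_table(ds),
                     file.path(out_path, "parameters.csv"),
                     row.names = FALSE)
  }
  ds
}

#' @export
print.tumor_dataset <- function(x, ...) {
  cat("Synthetic tumor dataset: ", length(x$records), " records over ",
      length(x$manifest$subjects), " subjects (", length(x$train_idx),
      " train / ", length(x$test_idx), " test, subject-wise split)\n",
      sep = "")
  invisible(x)
}

#' Parameter table of a tumor dataset
#' @param dataset a \code{\link{build_dataset}} result.
#' @return data.frame with one row per record.
#' @export
dataset_parameter_table <- function(dataset) {
  do.call(rbind, lapply(seq_along(dataset$records), function(i) {
    r <- dataset$records[[i]]
    p <- r$parameters
    data.frame(record = i, subject = r$subject_id,
               lambda = p$lambda, v = p$v, dwhite = p$dwhite, rho = p$rho,
               t1 = p$t1, t2 = p$t2, t3 = p$t3, t4 = p$t4,
               rejections = r$provenance$rejections,
               test = i %in% dataset$test_idx)
  }))
}
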
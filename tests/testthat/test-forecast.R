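test_that("post-processing applies its three rules in order and is idempotent", {
  ph <- phantom_folded_2d()
  dims <- ph$map$dim
  v <- array(0, dims)
  dom <- array(ph$map$labels %in% 2:3, dims)
  # main blob around an interior domain voxel
  ctr <- which(ph$map$labels == 3L, arr.ind = TRUE)[10, ]
  v[ctr[1] + (-2:2), ctr[2] + (-2:2), 1] <- 0.8
  v[ctr[1], ctr[2], 1] <- 1.0003                 # overshoot to clip
  csf_or_bg <- which(!dom, arr.ind = TRUE)
  v[csf_or_bg[1, 1], csf_or_bg[1, 2], 1] <- 1e-5 # non-brain leak to zero
  # far 2-voxel blob, disconnected from the main tumor
  far <- which(ph$map$labels == 2L, arr.ind = TRUE)
  far <- far[which.max(abs(far[, 1] - ctr[1]) + abs(far[, 2] - ctr[2])), ]
  v[far[1], far[2], 1] <- 1e-5
  raw <- list(values = v, spacing = ph$map$spacing, time = 200, dim = dims)

  post <- postprocess_density(raw, ph$map)
  expect_equal(max(post$values), 1)              # clipped
  expect_equal(post$values[csf_or_bg[1, 1], csf_or_bg[1, 2], 1], 0)
  expect_equal(post$values[far[1], far[2], 1], 0) # far blob removed
  expect_gt(post$values[ctr[1] + 1, ctr[2], 1], 0)
  twice <- postprocess_density(post, ph$map)
  expect_equal(twice$values, post$values)

  zero <- list(values = array(0, dims), spacing = ph$map$spacing,
               time = 0, dim = dims)
  expect_warning(postprocess_density(zero, ph$map), "zero")
})

test_that("forecasting from the true state and parameters reproduces the record", {
  rec <- study_record()
  sub <- attr(rec, "subject")
  fc <- forecast_density(rec$snapshots[[2]], rec$parameters$dwhite,
                         rec$parameters$rho, sub$unit_tensor, sub$map,
                         horizons = c(90, 180),
                         config = simulation_config(dt = 2))
  expect_lt(max(abs(fc[[1]]$values - rec$snapshots[[3]]$values)), 1e-10)
  expect_lt(max(abs(fc[[2]]$values - rec$snapshots[[4]]$values)), 1e-10)
  expect_equal(fc[[1]]$time, unname(rec$times[["t3"]]))
  expect_equal(fc[[2]]$time, unname(rec$times[["t4"]]))
})

test_that("a zero state forecasts to zero", {
  rec <- study_record()
  sub <- attr(rec, "subject")
  zero <- density_field(array(0, sub$map$dim), sub$map$spacing, 100)
  fc <- forecast_density(zero, 20, 10, sub$unit_tensor, sub$map,
                         config = simulation_config(dt = 2))
  expect_true(all(vapply(fc, function(f) all(f$values == 0), logical(1))))
})

test_that("forecast evaluation reports the full metric grid", {
  rec <- study_record()
  sub <- attr(rec, "subject")
  rep0 <- evaluate_forecast(rec, rec$snapshots[[2]], NULL,
                            sub$unit_tensor, sub$map,
                            config = simulation_config(dt = 2))
  expect_setequal(names(rep0$metrics),
                  c("time", "mae", "hausdorff_c1", "assd_c1",
                    "hausdorff_c2", "assd_c2"))
  expect_equal(rep0$metrics$time, unname(rec$times[c("t2", "t3", "t4")]))
  expect_true(all(abs(as.matrix(rep0$metrics[, -1])) < 1e-12))

  # same dwhite but doubled rho: lambda / sqrt(2), v * sqrt(2)
  bad <- glioma_estimate(rec$parameters$lambda / sqrt(2),
                         rec$parameters$v * sqrt(2), method = "network")
  expect_equal(bad$dwhite, rec$parameters$dwhite, tolerance = 1e-12)
  expect_equal(bad$rho, 2 * rec$parameters$rho, tolerance = 1e-12)
  repb <- evaluate_forecast(rec, rec$snapshots[[2]], bad,
                            sub$unit_tensor, sub$map,
                            config = simulation_config(dt = 2))
  expect_gte(repb$metrics$mae[3], repb$metrics$mae[1])
  expect_equal(unname(repb$parameter_errors[["rho"]]), 1)
  med <- summarize_forecasts(list(rep0, repb))
  expect_equal(nrow(med), 3)
  expect_true(all(c("median_mae", "n_undefined") %in% names(med)))
})

test_that("threshold sensitivity emits one row per perturbation combination", {
  ds <- study_dataset()
  subjects <- attr(ds, "subjects")
  # fast stand-in estimator: reads the truth, plus a threshold-dependent bias
  estimator <- function(record, thresholds) {
    bias <- 1 + (thresholds[1] - 0.80) + (thresholds[2] - 0.16)
    glioma_estimate(record$parameters$lambda * bias,
                    record$parameters$v * bias, method = "network")
  }
  idx <- ds$test_idx[1:5]
  out <- sensitivity_analysis(ds, estimator, record_idx = idx)
  expect_equal(nrow(out), 4)
  expect_setequal(paste(out$p_c1, out$p_c2),
                  c("-0.1 -0.1", "-0.1 0.1", "0.1 -0.1", "0.1 0.1"))
  base <- sensitivity_analysis(ds, estimator,
                               perturbations = data.frame(p1 = 0, p2 = 0),
                               record_idx = idx)
  expect_equal(base$mre_lambda, 0, tolerance = 1e-12)
  expect_equal(base$ccc_v, 1, tolerance = 1e-12)
  expect_error(
    sensitivity_analysis(ds, estimator,
                         perturbations = data.frame(p1 = 0.5, p2 = 0),
                         record_idx = idx),
    "outside")

  # lowering a threshold can only grow the visible region
  rec <- ds$records[[idx[1]]]
  lo <- threshold_region(rec$snapshots[[2]], 0.80 * 0.9)$mask
  hi <- threshold_region(rec$snapshots[[2]], 0.80)$mask
  expect_false(any(hi & !lo))
})
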
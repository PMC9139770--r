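test_that("diffusivity and proliferation derive from the wave relations", {
  r <- derive_rates(1, 2)
  expect_equal(r$dwhite, 1)
  expect_equal(r$rho, 1)
  # worked example: first tumor of the simulation gallery
  r <- derive_rates(1.71, 37.16)
  expect_equal(round(r$dwhite, 2), 31.77)
  expect_equal(round(r$rho, 2), 10.87)
  expect_equal(2 * sqrt(r$dwhite * r$rho), 37.16, tolerance = 1e-12)
  expect_equal(sqrt(r$dwhite / r$rho), 1.71, tolerance = 1e-12)
  expect_error(derive_rates(-1, 2), "positive")
})

test_that("sampled parameters stay inside the configured box", {
  rng <- sampling_ranges()
  draws <- lapply(1:2000, function(s) sample_parameters(rng, seed = s))
  lam <- vapply(draws, `[[`, numeric(1), "lambda")
  v <- vapply(draws, `[[`, numeric(1), "v")
  dt1 <- vapply(draws, `[[`, numeric(1), "dt1")
  dt2 <- vapply(draws, `[[`, numeric(1), "dt2")
  expect_true(all(lam >= 0.5 & lam <= 2.0))
  expect_true(all(v >= 28.28 & v <= 48.99))
  expect_true(all(dt1 %in% 90:180) && all(dt2 %in% 90:180))
  expect_true(all(dt1 == round(dt1)))
  # both integer endpoints actually occur
  expect_true(any(dt1 == 90L) && any(dt1 == 180L))
  # round-trip algebra holds for every draw
  for (d in draws[1:50]) {
    expect_equal(2 * sqrt(d$dwhite * d$rho), d$v, tolerance = 1e-12)
    expect_equal(sqrt(d$dwhite / d$rho), d$lambda, tolerance = 1e-12)
  }
  expect_identical(sample_parameters(rng, seed = 1),
                   sample_parameters(rng, seed = 1))
})

test_that("derived-rate marginals match the change-of-variables distribution", {
  rng <- sampling_ranges()
  n <- 1e4
  draws <- vapply(1:n, function(s) {
    p <- sample_parameters(rng, seed = 20000 + s)
    c(p$dwhite, p$rho)
  }, numeric(2))
  # direct construction from the defining transformation of independent
  # uniforms is the change-of-variables reference sample
  set.seed(99)
  lam <- runif(n, 0.5, 2); v <- runif(n, 28.28, 48.99)
  ks_d <- suppressWarnings(stats::ks.test(draws[1, ], lam * v / 2))
  ks_r <- suppressWarnings(stats::ks.test(draws[2, ], v / (2 * lam)))
  expect_gt(ks_d$p.value, 0.01)
  expect_gt(ks_r$p.value, 0.01)
  # joint samples stay inside the curvilinear image of the (lambda, v) box
  dw <- draws[1, ]; rho <- draws[2, ]
  lam_back <- sqrt(dw / rho); v_back <- 2 * sqrt(dw * rho)
  expect_true(all(lam_back >= 0.5 - 1e-9 & lam_back <= 2 + 1e-9))
  expect_true(all(v_back >= 28.28 - 1e-9 & v_back <= 48.99 + 1e-9))
})

test_that("synthesized records follow the imaging schedule and invariants", {
  rec <- study_record()
  expect_equal(unname(rec$times[["t3"]] - rec$times[["t2"]]), 90)
  expect_equal(unname(rec$times[["t4"]] - rec$times[["t3"]]), 90)
  # times live on the solver step grid, within half a step of the nominal
  expect_lte(abs(rec$times[["t1"]] - rec$parameters$dt1), 1)
  expect_gt(sum(rec$snapshots[[2]]$values >= 0.80), 0)   # visible core at t2
  sub <- attr(rec, "subject")
  dom <- sub$map$labels %in% 2:3
  for (s in rec$snapshots) {
    expect_gte(min(s$values), 0)
    expect_lte(max(s$values), 1 + 1e-6)
    expect_equal(max(abs(s$values[!dom])), 0)
  }
})

test_that("dataset assembly produces the subject-wise split deterministically", {
  subjects <- study_subjects(3, shape = c(32, 32, 1), spacing = 2.5)
  ds <- build_dataset(subjects, 4, seed = 5,
                      config = simulation_config(dt = 2))
  expect_equal(length(ds$records), 12)
  expect_equal(length(ds$train_idx), 8)
  expect_equal(length(ds$test_idx), 4)
  expect_true(all(vapply(ds$records[ds$test_idx], `[[`, character(1),
                         "subject_id") == "s03"))
  tab <- dataset_parameter_table(ds)
  expect_equal(nrow(tab), 12)

  ds2 <- build_dataset(subjects, 4, seed = 5,
                       config = simulation_config(dt = 2))
  expect_identical(dataset_parameter_table(ds2), tab)
  expect_error(build_dataset(subjects[1], 2), "at least 2 subjects")
})

test_that("records store the imaging-threshold regions for network input", {
  ds <- study_dataset()
  rec <- ds$records[[1]]
  expect_equal(rec$regions$core_t2$threshold, 0.80)
  expect_equal(rec$regions$edema_t2$threshold, 0.16)
  expect_equal(rec$regions$edema_t1$threshold, 0.16)
  expect_equal(rec$regions$edema_t1$time, unname(rec$times[["t1"]]))
  # core region is nested in the edema region
  expect_false(any(rec$regions$core_t2$mask & !rec$regions$edema_t2$mask))
})
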
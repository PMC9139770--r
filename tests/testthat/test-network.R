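test_that("target standardization uses the uniform moments and inverts", {
  expect_equal(unname(standardize_targets(1.25, 38.635)[1, ]), c(0, 0))
  expect_equal(unname(standardize_targets(2, 38.635)[1, 1]), sqrt(3),
               tolerance = 1e-12)
  set.seed(3)
  lam <- runif(1e4, 0.5, 2); v <- runif(1e4, 28.28, 48.99)
  z <- standardize_targets(lam, v)
  back <- destandardize_targets(z)
  expect_lt(max(abs(back[, "lambda"] - lam)), 1e-12)
  expect_lt(max(abs(back[, "v"] - v)), 1e-12)
  expect_error(standardize_targets(1, 1, sampling_ranges(lambda = c(1, 1))),
               "min < max")
})

test_that("the full-scale regressor merges a 145-component vector", {
  spec <- parameter_network_spec()
  expect_equal(spec$pre_output_length, 145L)
  expect_equal(unname(spec$terminal_shape), c(3L, 3L, 2L))
  net <- build_parameter_network(spec, seed = 0)
  dense <- net$layers[[length(net$layers)]]
  expect_equal(dim(dense$w), c(145L, 2L))
})

test_that("scaled-down regressors expose the right geometry and 2 outputs", {
  spec <- parameter_network_spec(c(64, 64), channels = 9,
                                 widths = c(8, 8, 8, 8))
  expect_equal(spec$pre_output_length, 4 * 4 * 8 + 1)
  net <- build_parameter_network(spec, seed = 1)
  x <- array(rnorm(64 * 64 * 9), c(64, 64, 1, 9))
  out <- gliogrow:::forward_parameter_network(net, x, 120)
  expect_length(out$y, 2)
  expect_error(parameter_network_spec(c(60, 60), widths = c(8, 8, 8, 8)),
               "divisible")
})

test_that("the density U-Net maps inputs to a same-size density map", {
  spec <- density_network_spec(c(192, 192, 128))
  expect_equal(unname(spec$input_shape %/% 2^spec$depth), c(12L, 12L, 8L))

  spec2 <- density_network_spec(c(64, 64), channels = 8, depth = 4,
                                base_width = 8)
  net <- build_density_network(spec2, seed = 1)
  x <- array(rnorm(64 * 64 * 8), c(64, 64, 1, 8))
  out <- gliogrow:::forward_density_network(net, x)
  expect_equal(dim(out$y), c(64L, 64L, 1L, 1L))
  expect_error(density_network_spec(c(60, 60)), "divisible")
})

test_that("analytic gradients match finite differences", {
  spec <- parameter_network_spec(c(8, 8), channels = 2, widths = c(3, 2))
  net <- build_parameter_network(spec, seed = 1)
  set.seed(4)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  tgt <- c(0.3, -0.2); dt2 <- 120
  fwd <- gliogrow:::forward_parameter_network(net, x, dt2, keep_cache = TRUE)
  gr <- gliogrow:::backward_parameter_network(net, fwd, 2 * (fwd$y - tgt) / 2)
  loss <- function(m) {
    f <- gliogrow:::forward_parameter_network(m, x, dt2)
    mean((f$y - tgt)^2)
  }
  eps <- 1e-6
  for (li in c(1, 4, length(net$layers))) {
    for (k in sample(length(net$layers[[li]]$w), 3)) {
      m2 <- net
      m2$layers[[li]]$w[k] <- m2$layers[[li]]$w[k] + eps
      num <- (loss(m2) - loss(net)) / eps
      expect_equal(gr[[li]]$dw[k], num, tolerance = 1e-3)
    }
  }

  uspec <- density_network_spec(c(16, 16), channels = 3, depth = 2,
                                base_width = 4)
  unet <- build_density_network(uspec, seed = 2)
  xu <- array(rnorm(16 * 16 * 3), c(16, 16, 1, 3))
  tu <- array(rnorm(16 * 16), c(16, 16, 1, 1))
  fu <- gliogrow:::forward_density_network(unet, xu, keep_cache = TRUE)
  dy <- sign(fu$y - tu) / length(tu); dim(dy) <- dim(tu)
  gu <- gliogrow:::backward_density_network(unet, fu, dy)
  lossu <- function(m)
    mean(abs(gliogrow:::forward_density_network(m, xu)$y - tu))
  for (b in 1:2) for (l in 1:3) {
    k <- sample(length(unet$up[[b]][[l]]$w), 1)
    m2 <- unet
    m2$up[[b]][[l]]$w[k] <- m2$up[[b]][[l]]$w[k] + eps
    num <- (lossu(m2) - lossu(unet)) / eps
    expect_equal(gu$up[[b]][[l]]$dw[k], num, tolerance = 1e-3)
  }
  k <- sample(length(unet$out[[3]]$w), 1)
  m2 <- unet; m2$out[[3]]$w[k] <- m2$out[[3]]$w[k] + eps
  expect_equal(gu$out[[3]]$dw[k], (lossu(m2) - lossu(unet)) / eps,
               tolerance = 1e-3)
})

test_that("augmentation shifts all channels and the target identically", {
  x <- array(rnorm(12 * 10 * 1 * 3), c(12, 10, 1, 3))
  s <- gliogrow:::shift_array(x, c(3, -2, 0))
  expect_equal(s[4:12, 1:8, 1, ], x[1:9, 3:10, 1, ])
  expect_true(all(s[1:3, , , ] == 0) && all(s[, 9:10, , ] == 0))
  # the channel-wise cross-correlation peak sits at the same offset for all
  s2 <- gliogrow:::shift_array(x, c(3, 0, 0))
  for (ch in 1:3) {
    cc <- which.max(sapply(-4:4, function(o)
      sum(gliogrow:::shift_array(x, c(o, 0, 0))[, , , ch] * s2[, , , ch])))
    expect_equal((-4:4)[cc], 3)
  }
})

test_that("the convolutional trunk is translation-consistent in the interior", {
  spec <- density_network_spec(c(64, 64), channels = 2, depth = 2,
                               base_width = 4)
  net <- build_density_network(spec, seed = 3)
  set.seed(9)
  x <- array(0, c(64, 64, 1, 2))
  x[25:40, 25:40, 1, ] <- rnorm(16 * 16 * 2)
  sh <- c(4, 4, 0)                     # a multiple of the total stride
  xs <- gliogrow:::shift_array(x, sh)
  y <- gliogrow:::forward_density_network(net, x)$y
  ys <- gliogrow:::forward_density_network(net, xs)$y
  y_shift <- gliogrow:::shift_array(y, sh)
  interior <- 20:56
  expect_equal(ys[interior, interior, 1, 1], y_shift[interior, interior, 1, 1],
               tolerance = 1e-8)
})

test_that("a short training run reduces the loss and early stopping triggers", {
  subjects <- study_subjects(2, shape = c(16, 16, 1), spacing = 4)
  ds <- build_dataset(subjects, 10, seed = 9,
                      config = simulation_config(dt = 2))
  ut <- lapply(subjects, `[[`, "unit_tensor")
  spec <- parameter_network_spec(c(16, 16), channels = 9, widths = c(6, 6))
  net <- build_parameter_network(spec, seed = 1)
  tr <- train_network(net, ds, ut,
                      training_config(lr = 1e-3, max_epochs = 15,
                                      patience = 15, shift = 2, seed = 1))
  expect_lt(tail(tr$history$train_loss, 1), tr$history$train_loss[1])
  expect_true(all(diff(tr$history$epoch) == 1))

  # zero learning rate: the test loss never improves after epoch 1, so
  # training must stop by epoch 1 + patience
  tr0 <- train_network(net, ds, ut,
                       training_config(lr = 0, max_epochs = 100,
                                       patience = 4, shift = 0, seed = 1))
  expect_lte(nrow(tr0$history), 5)
  expect_equal(tr0$best_epoch, 1)
})

test_that("training a tiny U-Net on the density task runs end to end", {
  subjects <- study_subjects(2, shape = c(16, 16, 1), spacing = 4)
  ds <- build_dataset(subjects, 6, seed = 12,
                      config = simulation_config(dt = 2))
  ut <- lapply(subjects, `[[`, "unit_tensor")
  spec <- density_network_spec(c(16, 16), channels = 8, depth = 2,
                               base_width = 4)
  net <- build_density_network(spec, seed = 2)
  tr <- train_network(net, ds, ut,
                      training_config(lr = 1e-3, max_epochs = 8,
                                      patience = 8, shift = 2, seed = 2))
  expect_lt(tail(tr$history$train_loss, 1), tr$history$train_loss[1])
  est <- predict(tr$model, ds$records[[ds$test_idx[1]]], ut$s02)
  expect_equal(dim(est$values), c(16L, 16L, 1L))
})
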
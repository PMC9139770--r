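test_that("seed placement fills the full neighborhood and is deterministic", {
  labs <- array(0L, c(9, 9, 9))
  labs[3:7, 3:7, 3:7] <- 2L
  labs[5, 5, 5] <- 3L                       # exactly one eligible white voxel
  bm <- brain_map(labs, 1)
  pl <- place_seed(bm, seed = 1)
  expect_equal(unname(pl$center), c(5L, 5L, 5L))
  expect_equal(sum(pl$field$values), 27)
  expect_true(all(pl$field$values[4:6, 4:6, 4:6] == 1))

  ph <- phantom_3d()
  expect_identical(place_seed(ph$map, seed = 4), place_seed(ph$map, seed = 4))
})

test_that("seeding fails when no white voxel has an interior neighborhood", {
  labs <- array(0L, c(9, 9, 1))
  labs[3, 3:6, 1] <- 3L                     # white strip on the domain edge
  bm <- brain_map(labs, 1)
  expect_error(place_seed(bm), "no white-matter voxel")
})

test_that("stability bound behaves as the explicit-Euler theory predicts", {
  zero <- tensor_field(matrix(0, 8, 6), dim = c(2, 2, 2), spacing = 1)
  expect_identical(stability_limit(zero), Inf)

  d <- 48.99   # the largest sampled white-matter diffusivity, mm^2/year
  comps <- matrix(rep(c(d, 0, 0, d, 0, d), each = 8), 8, 6)
  iso <- tensor_field(comps, dim = c(2, 2, 2), spacing = 1)
  expect_gt(stability_limit(iso), 0.5)
  expect_equal(stability_limit(iso, spacing = 2), 4 * stability_limit(iso))
})

test_that("dt above the stability bound is refused with the bound reported", {
  ph <- phantom_folded_2d()
  tens <- scale_tumor_tensor(ph$unit, 49)
  bound <- stability_limit(tens)
  sd0 <- place_seed(ph$map, seed = 1)
  expect_error(
    simulate_growth(sd0$field, tens, 10, ph$map,
                    simulation_config(dt = bound * 2, snapshot_times = 10)),
    "stability bound")
})

test_that("pure diffusion conserves mass exactly on a non-convex domain", {
  ph <- phantom_folded_2d()
  tens <- scale_tumor_tensor(ph$unit, 30)
  sd0 <- place_seed(ph$map, seed = 1)
  cfg <- simulation_config(dt = 0.5, snapshot_times = c(0, 20, 60),
                           clamp = FALSE)
  sn <- simulate_growth(sd0$field, tens, 0, ph$map, cfg)
  m <- vapply(sn, total_cell_mass, numeric(1))
  expect_lt(max(abs(m - m[1])) / m[1], 1e-10)
})

test_that("one raw step changes mass exactly by the logistic reaction", {
  ph <- phantom_folded_2d()
  tens <- scale_tumor_tensor(ph$unit, 20)
  sd0 <- place_seed(ph$map, seed = 2)
  rho <- 15; dt <- 0.5
  sn <- simulate_growth(sd0$field, tens, rho, ph$map,
                        simulation_config(dt = dt, snapshot_times = dt,
                                          clamp = FALSE))
  c0 <- sd0$field$values
  expected <- total_cell_mass(sd0$field) +
    dt * sum(rho / 365 * c0 * (1 - c0)) * prod(sd0$field$spacing)
  expect_equal(total_cell_mass(sn[[1]]), expected, tolerance = 1e-12)
})

test_that("zero initial density is a fixed point and D = 0 gives logistic growth", {
  labs <- array(3L, c(8, 8, 1))
  labs[c(1, 8), , ] <- 0L; labs[, c(1, 8), ] <- 0L
  bm <- brain_map(labs, 1)
  zero <- tensor_field(matrix(0, 64, 6), dim = c(8, 8, 1), spacing = 1)
  empty <- density_field(array(0, c(8, 8, 1)), 1, 0)
  sn <- simulate_growth(empty, zero, 20, bm,
                        simulation_config(0.5, c(50, 200)))
  expect_true(all(vapply(sn, function(f) all(f$values == 0), logical(1))))

  c0 <- density_field(array(0.5 * (labs == 3L), c(8, 8, 1)), 1, 0)
  rho <- 2                                   # per year
  t_ln3 <- log(3) / rho * 365                # c: 0.5 -> 0.75 in closed form
  sn <- simulate_growth(c0, zero, rho, bm, simulation_config(0.5, t_ln3))
  inside <- sn[[1]]$values[labs == 3L]
  expect_lt(max(abs(inside - 0.75)), 1e-3)
  expect_lte(abs(sn[[1]]$time - t_ln3), 0.25)   # snapshot at nearest step
})

test_that("fronts travel at the Fisher speed with the predicted tail decay", {
  d <- 12; rho <- 12          # lambda = 1 mm, v = 24 mm/year
  h <- 0.2; n <- 480
  labs <- array(3L, c(n, 1, 1)); labs[c(1, n), , ] <- 0L
  bm <- brain_map(labs, h)
  comps <- matrix(0, n, 6); comps[, c(1, 4, 6)] <- d
  tens <- tensor_field(comps, dim = c(n, 1, 1), spacing = h)
  v0 <- array(0, c(n, 1, 1)); v0[2:5, , ] <- 1
  times <- seq(800, 1200, by = 50)
  sn <- simulate_growth(density_field(v0, h, 0), tens, rho, bm,
                        simulation_config(0.5, times))
  front <- vapply(sn, function(f) {
    cv <- f$values[, 1, 1]
    i <- max(which(cv >= 0.5))
    (i - 1) * h + h * (cv[i] - 0.5) / (cv[i] - cv[i + 1])
  }, numeric(1))
  speed <- unname(coef(lm(front ~ times))[2]) * 365
  expect_lt(abs(speed - 2 * sqrt(d * rho)) / (2 * sqrt(d * rho)), 0.05)

  cv <- sn[[length(sn)]]$values[, 1, 1]
  sel <- which(cv > 1e-6 & cv < 1e-2)
  slope <- unname(coef(lm(log(cv[sel]) ~ I((sel - 1) * h)))[2])
  expect_lt(abs(-1 / slope - sqrt(d / rho)) / sqrt(d / rho), 0.10)
})

test_that("clamped runs stay inside the density band and report clipped mass", {
  ph <- phantom_folded_2d()
  tens <- scale_tumor_tensor(ph$unit, 40)
  sd0 <- place_seed(ph$map, seed = 5)
  sn <- simulate_growth(sd0$field, tens, 12, ph$map,
                        simulation_config(0.5, c(100, 250)))
  for (f in sn) {
    expect_gte(min(f$values), 0)
    expect_lte(max(f$values), 1)
    expect_equal(max(abs(f$values[!(ph$map$labels %in% 2:3)])), 0)
  }
  expect_gte(attr(sn, "clipped_mass"), 0)
})
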
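test_that("generated phantoms satisfy the label-map invariants", {
  ph <- phantom_3d()
  labs <- ph$map$labels
  expect_true(all(labs %in% 0:3))
  expect_gt(sum(labs == 3L), 0)
  # background margin on every face: the brain never touches the grid
  dom <- labs == 2L | labs == 3L
  expect_false(any(dom[1, , ]) || any(dom[dim(labs)[1], , ]))
  expect_false(any(dom[, 1, ]) || any(dom[, dim(labs)[2], ]))
  expect_false(any(dom[, , 1]) || any(dom[, , dim(labs)[3]]))
})

test_that("phantom generation is deterministic per seed and styles differ", {
  a <- generate_brain_phantom(c(24, 24, 1), 1.5, "folded", seed = 11)
  b <- generate_brain_phantom(c(24, 24, 1), 1.5, "folded", seed = 11)
  expect_identical(a, b)
  c <- generate_brain_phantom(c(24, 24, 1), 1.5, "folded", seed = 12)
  expect_false(identical(a$map$labels, c$map$labels))
})

test_that("white matter stays within the requested shell radius", {
  ph <- generate_brain_phantom(c(32, 32, 32), 1, "two-shell", seed = 0,
                               gray_radius = 12, white_radius = 8)
  idx <- which(ph$map$labels == 3L, arr.ind = TRUE)
  center <- (dim(ph$map$labels) - 1) / 2
  r <- sqrt(rowSums(sweep(idx - 1, 2, center, "-")^2))
  expect_true(all(r < 8))
})

test_that("water tensors are PSD, anisotropic in white and zero outside", {
  ph <- phantom_3d()
  labs <- as.vector(ph$map$labels)
  expect_gte(min(min_tensor_eigenvalues(ph$water)), -1e-12)
  expect_equal(max(abs(ph$water$components[!(labs %in% 2:3), ])), 0)
  widx <- which(labs == 3L)
  cl <- vapply(widx[seq(1, length(widx), by = 7)], function(i) {
    ev <- sort(eigen(sym33(ph$water$components[i, ]), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    westin_measures(ev)[["cl"]]
  }, numeric(1))
  expect_gt(max(cl), 0.5)
})

test_that("degenerate phantom requests are rejected", {
  expect_error(generate_brain_phantom(c(8, 8, 8)), "too small")
  expect_error(generate_brain_phantom(c(32, 32, 1), style = "spiral"))
  expect_error(generate_brain_phantom(c(32, 32, 1), gray_radius = 30),
               "margin")
})

test_that("brain maps round-trip through NIfTI with spacing", {
  ph <- phantom_3d()
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_brain_map(ph$map, f)
  back <- load_brain_map(f)
  expect_identical(back$labels, ph$map$labels)
  expect_equal(back$spacing, ph$map$spacing)
})

test_that("label validation names offending values and flags missing white", {
  labs <- array(0L, c(16, 16, 4))
  labs[4:8, 4:8, 2] <- 7L
  f <- withr::local_tempfile(fileext = ".nii.gz")
  im <- RNifti::asNifti(labs)
  RNifti::writeNifti(im, f)
  expect_error(load_brain_map(f), "\\{7\\}")

  labs[labs == 7L] <- 2L   # gray only, no white
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(labs), f2)
  expect_warning(load_brain_map(f2), "no white-matter")
})

test_that("tensor fields round-trip and component dialects agree", {
  ph <- phantom_3d()
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_tensor_field(ph$water, f)
  back <- load_water_tensor(f, "lower-triangular")
  expect_equal(back$components, ph$water$components, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$spacing, ph$water$spacing)

  # the same random field written diagonal-first reads back identically
  set.seed(5)
  comps <- matrix(rnorm(6 * 64), 64, 6)
  comps <- t(apply(comps, 1, function(cc) {   # make PSD via A A^T
    M <- sym33(cc); M <- M %*% t(M)
    c(M[1, 1], M[1, 2], M[1, 3], M[2, 2], M[2, 3], M[3, 3])
  }))
  arr_lt <- array(comps, c(4, 4, 4, 6))
  arr_df <- arr_lt[, , , c(1, 4, 6, 2, 3, 5)]  # (xx,yy,zz,xy,xz,yz)
  f1 <- withr::local_tempfile(fileext = ".nii")
  f2 <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(arr_lt), f1)
  RNifti::writeNifti(RNifti::asNifti(arr_df), f2)
  a <- load_water_tensor(f1, "lower-triangular")
  b <- load_water_tensor(f2, "diagonal-first")
  expect_equal(a$components, b$components, tolerance = 1e-6)
})

test_that("negative water-tensor eigenvalues are clamped and counted", {
  comps <- matrix(0, 8, 6)
  comps[, c(1, 4, 6)] <- 1e-3          # isotropic, fine
  comps[3, c(1, 4, 6)] <- c(1e-3, 1e-3, -1e-5)  # one negative eigenvalue
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(comps, c(2, 2, 2, 6))), f)
  expect_message(tf <- load_water_tensor(f, "lower-triangular"),
                 "clamped .* 1 voxel")
  expect_equal(attr(tf, "n_clamped"), 1L)
  expect_gte(min(min_tensor_eigenvalues(tf)), -1e-12)
  expect_equal(tf$components[3, c(1, 4)], c(xx = 1e-3, yy = 1e-3),
               tolerance = 1e-9)
  expect_equal(unname(tf$components[3, 6]), 0, tolerance = 1e-12)
})
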
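#' Generate a synthetic brain phantom with a water diffusion tensor field
#'
#' Builds a closed brain domain made of a gray-matter shell surrounding a
#' white-matter core (with a small central CSF cavity), together with a
#' spatially varying, symmetric positive-semidefinite water diffusion tensor
#' field: strongly anisotropic, fiber-like tensors oriented circumferentially
#' in white matter and near-isotropic tensors in gray matter. The
#' \code{"folded"} style modulates the shell radii sinusoidally to produce a
#' non-convex domain exercising boundary handling. The brain never touches
#' the grid boundary, so a background margin exists on all faces.
#'
#' @param shape grid dimensions (length 3; a singleton dimension gives a 2D
#'   slab phantom). Every non-singleton dimension must be at least 16.
#' @param spacing voxel edge length(s) in mm.
#' @param style \code{"two-shell"} (spherical shells) or \code{"folded"}
#'   (sinusoidally perturbed shell boundaries).
#' @param seed integer RNG seed; equal seeds give bit-identical phantoms.
#' @param gray_radius,white_radius,csf_radius shell radii in mm; defaults
#'   scale with the grid extent.
#' @return list with elements \code{map} (a \code{\link{brain_map}}) and
#'   \code{water} (a \code{\link{tensor_field}}, arbitrary water-diffusivity
#'   units).
#' @export
generate_brain_phantom <- function(shape, spacing = 1,
                                   style = c("two-shell", "folded"),
                                   seed = 0,
                                   gray_radius = NULL, white_radius = NULL,
                                   csf_radius = NULL) {
  style <- match.arg(style)
  shape <- as.integer(rep_len(shape, 3))
  spacing <- rep_len(as.numeric(spacing), 3)
  active <- shape > 1
  if (any(shape[active] < 16))
    stop("shape too small: non-singleton dimensions must be >= 16 voxels")
  extent <- shape * spacing
  min_ext <- min(extent[active])
  if (is.null(gray_radius)) gray_radius <- 0.375 * min_ext
  if (is.null(white_radius)) white_radius <- 2 / 3 * gray_radius
  if (is.null(csf_radius)) csf_radius <- 0.25 * white_radius
  max_gray <- gray_radius * if (style == "folded") 1.12 else 1
  if (max_gray >= min_ext / 2 - max(spacing[active]) * 1.5)
    stop("gray_radius leaves no background margin inside the grid")
  if (white_radius >= gray_radius) stop("white_radius must be < gray_radius")

  center <- (shape - 1) / 2 * spacing
  co <- lapply(1:3, function(i) ((seq_len(shape[i]) - 1) * spacing[i]) - center[i])
  X <- array(co[[1]], dim = shape)
  Y <- array(rep(co[[2]], each = shape[1]), dim = shape)
  Z <- array(rep(co[[3]], each = shape[1] * shape[2]), dim = shape)
  r <- sqrt(X^2 + Y^2 + Z^2)

  with_seed(seed, {
    if (style == "folded") {
      ph1 <- runif(1, 0, 2 * pi)
      ph2 <- runif(1, 0, 2 * pi)
      theta <- atan2(Y, X)
      gray_r <- gray_radius * (1 + 0.12 * sin(3 * theta + ph1))
      white_r <- white_radius * (1 + 0.18 * sin(4 * theta + ph2))
    } else {
      gray_r <- gray_radius
      white_r <- white_radius
    }
    labels <- array(LABEL_BACKGROUND, dim = shape)
    labels[r < gray_r] <- LABEL_GRAY
    labels[r < white_r] <- LABEL_WHITE
    labels[r < csf_radius] <- LABEL_CSF

    n <- prod(shape)
    comps <- matrix(0, n, 6)
    white_idx <- which(labels == LABEL_WHITE)
    gray_idx <- which(labels == LABEL_GRAY)

    # gray matter: near-isotropic tensors with mild seeded jitter
    base_gray <- 0.8e-3
    jit <- matrix(runif(length(gray_idx) * 3, 0.95, 1.05), ncol = 3)
    comps[gray_idx, 1] <- base_gray * jit[, 1]
    comps[gray_idx, 4] <- base_gray * jit[, 2]
    comps[gray_idx, 6] <- base_gray * jit[, 3]

    # white matter: fiber-like tensors, principal axis circumferential
    ev <- c(1.7e-3, 0.4e-3, 0.2e-3)
    jw <- runif(length(white_idx), 0.95, 1.05)
    rx <- X[white_idx]; ry <- Y[white_idx]; rz <- Z[white_idx]
    rn <- pmax(sqrt(rx^2 + ry^2 + rz^2), 1e-9)
    rx <- rx / rn; ry <- ry / rn; rz <- rz / rn
    # e1 = normalize(ez x rhat) (in-plane tangential), fallback ex at poles
    tx <- -ry; ty <- rx; tz <- 0
    tn <- sqrt(tx^2 + ty^2)
    deg <- tn < 1e-6
    tx[deg] <- 1; ty[deg] <- 0; tn[deg] <- 1
    tx <- tx / tn; ty <- ty / tn
    # e2 = rhat x e1, e3 = rhat
    sx <- ry * tz - rz * ty; sy <- rz * tx - rx * tz; sz <- rx * ty - ry * tx
    l1 <- ev[1] * jw; l2 <- ev[2] * jw; l3 <- ev[3] * jw
    comps[white_idx, 1] <- l1 * tx * tx + l2 * sx * sx + l3 * rx * rx
    comps[white_idx, 2] <- l1 * tx * ty + l2 * sx * sy + l3 * rx * ry
    comps[white_idx, 3] <- l1 * tx * tz + l2 * sx * sz + l3 * rx * rz
    comps[white_idx, 4] <- l1 * ty * ty + l2 * sy * sy + l3 * ry * ry
    comps[white_idx, 5] <- l1 * ty * tz + l2 * sy * sz + l3 * ry * rz
    comps[white_idx, 6] <- l1 * tz * tz + l2 * sz * sz + l3 * rz * rz

    list(map = brain_map(labels, spacing),
         water = tensor_field(comps, dim = shape, spacing = spacing))
  })
}

#' Write a brain label map to NIfTI
#' @param map a \code{\link{brain_map}}.
#' @param path output file (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_brain_map <- function(map, path) {
  im <- RNifti::asNifti(map$labels)
  RNifti::pixdim(im) <- map$spacing
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Load a brain label map from NIfTI
#'
#' Labels must lie in \code{{0, 1, 2, 3}} (background, CSF, gray, white);
#' any other value is an error naming the offending labels. A map with no
#' white-matter voxels loads with a warning since seed placement will fail
#' on it. Anisotropic voxel spacing is accepted and reported.
#'
#' @param path NIfTI file with an integer-valued label volume.
#' @return A \code{\link{brain_map}} with spacing read from the header.
#' @export
load_brain_map <- function(path) {
  im <- RNifti::readNifti(path)
  vals <- as.vector(im)
  if (max(abs(vals - round(vals))) > 1e-6)
    stop("label volume is not integer-valued: ", path)
  labels <- array(as.integer(round(vals)), dim = dim(im))
  spacing <- RNifti::pixdim(im)[1:3]
  map <- brain_map(labels, spacing)
  if (!any(labels == LABEL_WHITE))
    warning("brain map has no white-matter voxels; seed placement will fail")
  if (max(spacing) - min(spacing) > 1e-6)
    message("anisotropic voxel spacing: ",
            paste(signif(spacing, 4), collapse = " x "), " mm")
  map
}

#' Write a 6-component tensor field to NIfTI
#' @param tensor a \code{\link{tensor_field}}.
#' @param path output file; components are stored along the 4th dimension in
#'   the internal order (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
#' @return \code{path}, invisibly.
#' @export
write_tensor_field <- function(tensor, path) {
  im <- RNifti::asNifti(tensor_array(tensor))
  RNifti::pixdim(im) <- c(tensor$spacing, 1)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Load a water diffusion tensor field from NIfTI
#'
#' Reads a 4D volume whose 4th dimension holds the 6 independent components
#' of a symmetric tensor, reorders them to the internal
#' (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz) convention, and clamps negative
#' eigenvalues (which occur in noisy DTI reconstructions) to zero so the
#' field is positive semidefinite. The number of clamped voxels is attached
#' as attribute \code{"n_clamped"} and reported.
#'
#' @param path NIfTI file with 6 components in the 4th dimension.
#' @param component_order \code{"lower-triangular"} for
#'   (xx, xy, xz, yy, yz, zz) or \code{"diagonal-first"} for
#'   (xx, yy, zz, xy, xz, yz).
#' @return A \code{\link{tensor_field}}.
#' @export
load_water_tensor <- function(path,
                              component_order = c("lower-triangular",
                                                  "diagonal-first")) {
  component_order <- match.arg(component_order)
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 4 || d[4] != 6)
    stop("tensor volume must have 6 components in the 4th dimension, got ",
         paste(d, collapse = " x "))
  comps <- matrix(as.numeric(im), nrow = prod(d[1:3]), ncol = 6)
  if (component_order == "diagonal-first")
    comps <- comps[, c(1, 4, 5, 2, 6, 3), drop = FALSE]
  cl <- clamp_psd_cpp(comps)
  if (cl$n_clamped > 0)
    message("clamped negative eigenvalues in ", cl$n_clamped, " voxels")
  tf <- tensor_field(cl$components, dim = d[1:3],
                     spacing = RNifti::pixdim(im)[1:3])
  attr(tf, "n_clamped") <- cl$n_clamped
  tf
}
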
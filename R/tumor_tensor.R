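#' Anisotropy settings for tumor tensor construction
#'
#' @param a anisotropy multiplier applied to the linear and planar shape
#'   fractions of the water tensor (dimensionless, >= 1; 10 mimics the
#'   preferential migration of tumor cells along white-matter tracts).
#' @param gray_ratio ratio of gray- to white-matter mean tumor diffusivity
#'   (default 0.1, reflecting restricted migration in gray matter).
#' @param dwhite white-matter mean tumor diffusivity in mm^2/year; 1 builds
#'   a unit tensor to be rescaled per tumor.
#' @return list of class \code{anisotropy_settings}.
#' @export
anisotropy_settings <- function(a = 10, gray_ratio = 0.1, dwhite = 1) {
  if (a < 1) stop("anisotropy factor a must be >= 1")
  if (gray_ratio <= 0) stop("gray_ratio must be positive")
  if (dwhite <= 0) stop("dwhite must be positive")
  structure(list(a = a, gray_ratio = gray_ratio, dwhite = dwhite),
            class = "anisotropy_settings")
}

#' Westin shape measures of a diffusion tensor
#'
#' Linear, planar and spherical anisotropy fractions of a symmetric tensor
#' with eigenvalues sorted in descending order:
#' \code{cl = (l1 - l2) / s}, \code{cp = 2 (l2 - l3) / s},
#' \code{cs = 3 l3 / s} with \code{s = l1 + l2 + l3}. The three measures
#' sum to 1 identically.
#'
#' @param eigenvalues numeric triple, sorted descending, all >= 0, not all
#'   zero.
#' @return named numeric vector \code{c(cl, cp, cs)}.
#' @export
westin_measures <- function(eigenvalues) {
  if (length(eigenvalues) != 3) stop("need exactly 3 eigenvalues")
  if (is.unsorted(rev(eigenvalues))) stop("eigenvalues must be sorted descending")
  if (any(eigenvalues < 0)) stop("eigenvalues must be non-negative")
  s <- sum(eigenvalues)
  if (s <= 0) stop("all-zero eigenvalues: shape measures undefined")
  c(cl = (eigenvalues[1] - eigenvalues[2]) / s,
    cp = 2 * (eigenvalues[2] - eigenvalues[3]) / s,
    cs = 3 * eigenvalues[3] / s)
}

#' Build the tumor cell diffusion tensor field
#'
#' Assembles the tumor tensor piecewise over the brain map: in white matter
#' the water tensor at each voxel is eigendecomposed, its eigenvalues are
#' reweighted by \code{l_i(a)} obtained from the matrix with rows
#' (a, a, 1), (1, a, 1), (1, 1, 1) acting on the Westin measures
#' (cl, cp, cs), and the result is rescaled so that its trace is exactly
#' \code{3 * dwhite}; in gray matter the tensor is the isotropic
#' \code{gray_ratio * dwhite * I}; in CSF and background it is zero. With
#' \code{a = 1} the white-matter tensor is the water tensor rescaled to mean
#' diffusivity \code{dwhite} (shape preserved).
#'
#' @param water water \code{\link{tensor_field}} (any diffusivity units).
#' @param brain a \code{\link{brain_map}} on the same grid.
#' @param settings an \code{\link{anisotropy_settings}}.
#' @return A \code{\link{tensor_field}} in mm^2/year (dimensionless when
#'   \code{dwhite = 1}).
#' @export
build_tumor_tensor <- function(water, brain, settings = anisotropy_settings()) {
  check_same_grid(water, brain, "water tensor and brain map")
  res <- build_tumor_tensor_cpp(water$components, as.vector(brain$labels),
                                settings$a, settings$gray_ratio,
                                settings$dwhite)
  if (length(res$bad_white_voxels) > 0)
    stop("white-matter voxels with zero water tensor (orientation undefined) ",
         "at linear indices: ",
         paste(utils::head(res$bad_white_voxels, 10), collapse = ", "),
         if (length(res$bad_white_voxels) > 10) " ..." else "")
  tensor_field(res$components, dim = water$dim, spacing = water$spacing)
}

#' Rescale a unit tumor tensor by a sampled white-matter diffusivity
#'
#' The unit tensor is built with \code{dwhite = 1}; the per-tumor field is a
#' scalar multiple, which preserves the fixed gray/white diffusivity ratio.
#'
#' @param unit_tensor unit tumor \code{\link{tensor_field}}.
#' @param dwhite white-matter mean diffusivity, mm^2/year.
#' @return A \code{\link{tensor_field}} in mm^2/year.
#' @export
scale_tumor_tensor <- function(unit_tensor, dwhite) {
  if (dwhite <= 0) stop("dwhite must be positive")
  tensor_field(unit_tensor$components * dwhite, dim = unit_tensor$dim,
               spacing = unit_tensor$spacing)
}

#' Minimum eigenvalue at every voxel of a tensor field
#' @param tensor a \code{\link{tensor_field}}.
#' @return numeric vector of per-voxel minimum eigenvalues.
#' @export
min_tensor_eigenvalues <- function(tensor) {
  min_eig_field_cpp(tensor$components)
}
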
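#' Masked mean absolute error between density fields
#'
#' Mean of \code{|true - est|} over the voxels where the TRUE density
#' exceeds \code{mask_threshold} (the c > 0.01 region), preventing
#' background and weakly invaded voxels from diluting the error. The mask is
#' taken from the true field so the estimate cannot shrink its own
#' evaluation region.
#'
#' @param true_c,est_c \code{\link{density_field}}s on the same grid.
#' @param mask_threshold density defining the evaluation region.
#' @return scalar MAE in normalized density units.
#' @export
masked_mae <- function(true_c, est_c, mask_threshold = 0.01) {
  check_same_grid(true_c, est_c, "density fields")
  mask <- true_c$values > mask_threshold
  if (!any(mask))
    stop("empty evaluation mask: no true density above ", mask_threshold)
  mean(abs(true_c$values[mask] - est_c$values[mask]))
}

as_surface_coords <- function(x, what) {
  if (inherits(x, "contour_surface") || is.matrix(x)) m <- unclass(x)
  else stop(what, " must be a contour_surface or coordinate matrix")
  m <- as.matrix(m)
  if (nrow(m) == 0) stop(what, " is an empty surface")
  m
}

#' Hausdorff distance between contour surfaces
#'
#' Maximum of the two directed max-min Euclidean distances between the
#' voxel-center coordinate sets, in mm. Symmetric in its arguments.
#'
#' @param A,B \code{\link{extract_surface}} results (or coordinate
#'   matrices), both non-empty.
#' @return scalar distance in mm.
#' @export
hausdorff_distance <- function(A, B) {
  set_distances_cpp(as_surface_coords(A, "A"), as_surface_coords(B, "B"))$hausdorff
}

#' Average symmetric surface distance between contour surfaces
#'
#' Sum over both surfaces of each voxel's distance to the nearest voxel of
#' the other surface, divided by the total number of surface voxels
#' \code{|A| + |B|}, in mm. Symmetric in its arguments.
#'
#' @inheritParams hausdorff_distance
#' @return scalar distance in mm.
#' @export
assd <- function(A, B) {
  set_distances_cpp(as_surface_coords(A, "A"), as_surface_coords(B, "B"))$assd
}

#' Lin's concordance correlation coefficient
#'
#' \code{2 cov(x, y) / (var x + var y + (mean x - mean y)^2)} with
#' population (1/n) moments, penalizing both dispersion and location shifts
#' between predictions and truth.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return scalar in [-1, 1].
#' @export
concordance_ccc <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 2) stop("need at least 2 observations")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) stop("degenerate inputs: zero variance and equal means")
  2 * cxy / denom
}

#' Relative error of an estimate
#'
#' \code{|est - true| / |true|}, vectorized over paired values; the median
#' over a test set is the usual summary.
#'
#' @param true true value(s), none zero.
#' @param est estimated value(s).
#' @return fraction(s) >= 0.
#' @export
relative_error <- function(true, est) {
  if (any(true == 0)) stop("relative error undefined for true value 0")
  abs(est - true) / abs(true)
}
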
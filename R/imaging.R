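#' Threshold imaging model: binary visible region
#'
#' Applies the cell-density threshold imaging function: a voxel appears
#' abnormal on a sequence iff \code{c >= c_seq}. Thresholds 0.80 and 0.16
#' mimic the contrast-enhancing core and the T2-FLAIR edema outline,
#' respectively. Regions are nested: a higher threshold gives a subset of a
#' lower one.
#'
#' @param field a \code{\link{density_field}}.
#' @param c_seq detectability threshold, strictly inside (0, 1).
#' @return list of class \code{binary_region} with logical \code{mask},
#'   \code{threshold}, \code{time}, \code{spacing}, \code{dim}.
#' @export
threshold_region <- function(field, c_seq) {
  if (!is.numeric(c_seq) || length(c_seq) != 1 || c_seq <= 0 || c_seq >= 1)
    stop("threshold must lie strictly inside (0, 1), got ", c_seq)
  mask <- field$values >= c_seq
  structure(list(mask = mask, threshold = c_seq, time = field$time,
                 spacing = field$spacing, dim = field$dim),
            class = "binary_region")
}

#' @export
print.binary_region <- function(x, ...) {
  cat("Binary region (c >= ", x$threshold, ") at t = ", x$time, " d: ",
      sum(x$mask), " voxels\n", sep = "")
  invisible(x)
}

#' Extract the contour surface of a binary region
#'
#' Surface voxels are region voxels with at least one 6-connected neighbor
#' outside the region; neighbors are taken along non-singleton axes only
#' (2D slabs have in-plane perimeters), and voxels on the grid boundary
#' count as surface. An empty region yields an empty surface.
#'
#' @param region a \code{\link{threshold_region}} result.
#' @return object of class \code{contour_surface}: a matrix of voxel-center
#'   physical coordinates in mm (possibly 0 rows), with the voxel linear
#'   indices as attribute \code{"voxels"}.
#' @export
extract_surface <- function(region) {
  idx <- surface_indices_cpp(as.vector(region$mask), region$dim)
  coords <- voxel_coordinates(idx, region$dim, region$spacing)
  structure(coords, voxels = idx, spacing = region$spacing,
            class = c("contour_surface", class(coords)))
}

# physical mm coordinates (0-based index times spacing) of linear voxel indices
voxel_coordinates <- function(idx, dim, spacing) {
  if (length(idx) == 0)
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z"))))
  a <- arrayInd(idx, dim)
  coords <- sweep(a - 1, 2, spacing, "*")
  colnames(coords) <- c("x", "y", "z")
  coords
}

#' @export
print.contour_surface <- function(x, ...) {
  cat("Contour surface: ", nrow(x), " voxels\n", sep = "")
  invisible(x)
}
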
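#' @useDynLib gliogrow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif median setNames coef predict
NULL

# Label encoding used package-wide: 0 background, 1 CSF, 2 gray, 3 white.
LABEL_BACKGROUND <- 0L
LABEL_CSF <- 1L
LABEL_GRAY <- 2L
LABEL_WHITE <- 3L

DAYS_PER_YEAR <- 365

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Brain label map
#'
#' A voxel volume of tissue labels with physical voxel spacing. The label
#' encoding is fixed package-wide: 0 = background, 1 = cerebrospinal fluid,
#' 2 = gray matter, 3 = white matter. The brain domain over which tumors
#' grow is the union of gray and white matter; CSF and background are
#' outside it and carry no tumor cells.
#'
#' @param labels integer 3D array of labels in \code{0:3} (a 2D problem uses
#'   a singleton third dimension).
#' @param spacing numeric voxel edge lengths in mm, length 1 or 3.
#' @return An object of class \code{brain_map} with elements \code{labels},
#'   \code{spacing} and \code{dim}.
#' @export
brain_map <- function(labels, spacing = 1) {
  if (length(dim(labels)) == 2) dim(labels) <- c(dim(labels), 1L)
  stopifnot(length(dim(labels)) == 3)
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  bad <- setdiff(unique(as.vector(labels)), 0:3)
  if (length(bad) > 0)
    stop("labels outside {0,1,2,3}: {", paste(sort(bad), collapse = ", "), "}")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = spacing, dim = dim(labels)),
            class = "brain_map")
}

#' @export
print.brain_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:3,
                      labels = c("background", "CSF", "gray", "white")))
  cat("Brain label map: ", paste(x$dim, collapse = " x "), " voxels, spacing ",
      paste(signif(x$spacing, 4), collapse = " x "), " mm\n", sep = "")
  print(tab)
  invisible(x)
}

# logical volume of the brain domain (gray + white)
brain_domain <- function(brain) {
  brain$labels == LABEL_GRAY | brain$labels == LABEL_WHITE
}

#' Symmetric diffusion tensor field
#'
#' Per-voxel symmetric 3x3 tensors stored as 6 components in the order
#' (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz). Water tensors carry arbitrary diffusivity
#' units; tumor tensors are in mm^2/year (dimensionless for unit tensors
#' built with a white-matter mean diffusivity of 1).
#'
#' @param components numeric matrix with one row per voxel and 6 columns, or
#'   a 4D array (x, y, z, 6).
#' @param dim grid dimensions (required when \code{components} is a matrix).
#' @param spacing voxel spacing in mm.
#' @return An object of class \code{tensor_field}.
#' @export
tensor_field <- function(components, dim = NULL, spacing = 1) {
  if (is.array(components) && length(base::dim(components)) == 4) {
    d4 <- base::dim(components)
    if (d4[4] != 6) stop("tensor array must have 6 components, got ", d4[4])
    dim <- d4[1:3]
    components <- matrix(components, nrow = prod(dim), ncol = 6)
  }
  if (is.null(dim)) stop("dim required for matrix components")
  dim <- as.integer(dim)
  if (nrow(components) != prod(dim)) stop("component rows do not match dim")
  spacing <- rep_len(as.numeric(spacing), 3)
  colnames(components) <- c("xx", "xy", "xz", "yy", "yz", "zz")
  structure(list(components = components, dim = dim, spacing = spacing),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  md <- mean_diffusivity(x)
  cat("Symmetric tensor field: ", paste(x$dim, collapse = " x "),
      " voxels, ", sum(md > 0), " non-zero tensors, max mean diffusivity ",
      signif(max(md), 4), "\n", sep = "")
  invisible(x)
}

#' Per-voxel mean diffusivity trace(D)/3 of a tensor field
#' @param tensor a \code{tensor_field}.
#' @return numeric vector, one value per voxel.
#' @export
mean_diffusivity <- function(tensor) {
  rowSums(tensor$components[, c("xx", "yy", "zz"), drop = FALSE]) / 3
}

# 4D array view (x, y, z, 6) of a tensor field
tensor_array <- function(tensor) {
  array(tensor$components, dim = c(tensor$dim, 6L))
}

#' Normalized tumor cell-density field
#'
#' Tumor cell density normalized by the tissue carrying capacity, so values
#' lie in \code{[0, 1]} (up to solver round-off) and are zero outside the
#' brain domain.
#'
#' @param values numeric 3D array of densities.
#' @param spacing voxel spacing in mm.
#' @param time time stamp in days since tumor emergence.
#' @return An object of class \code{density_field}.
#' @export
density_field <- function(values, spacing = 1, time = 0) {
  if (length(dim(values)) == 2) dim(values) <- c(dim(values), 1L)
  stopifnot(length(dim(values)) == 3)
  if (min(values) < -1e-9 || max(values) > 1 + 1e-6)
    stop("density values outside [0, 1] tolerance band: range ",
         paste(signif(range(values), 6), collapse = " .. "))
  structure(list(values = values, spacing = rep_len(as.numeric(spacing), 3),
                 time = as.numeric(time), dim = dim(values)),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat("Density field at t = ", x$time, " d: ", paste(x$dim, collapse = " x "),
      " voxels, total cell mass ", signif(total_cell_mass(x), 6),
      " (max c = ", signif(max(x$values), 4), ")\n", sep = "")
  invisible(x)
}

#' Total tumor cell mass of a density field
#'
#' Sum of densities weighted by the voxel volume, in mm^3 of fully invaded
#' tissue equivalent.
#' @param field a \code{density_field}.
#' @return scalar.
#' @export
total_cell_mass <- function(field) {
  sum(field$values) * prod(field$spacing)
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!identical(as.integer(a$dim), as.integer(b$dim)))
    stop(what, " have mismatched grid dimensions")
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop(what, " have mismatched voxel spacing")
  invisible(TRUE)
}
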
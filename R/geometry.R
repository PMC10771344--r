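#' Grid geometry for volumetric QSM data
#'
#' Describes the voxel grid every volume in a reconstruction shares: the
#' array shape, the voxel size in millimetres, and the direction of the
#' static field B0 in the laboratory frame. The B0 direction defaults to
#' +z (supine acquisition); tilted orientations are expressed by rotating
#' this vector rather than the data.
#'
#' @param shape integer vector of length 3, voxels along x, y, z (each >= 2).
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm.
#' @param b0_direction numeric unit 3-vector, direction of B0.
#' @return an object of class `grid_geometry`.
#' @export
grid_geometry <- function(shape, voxel_size = c(1, 1, 1),
                          b0_direction = c(0, 0, 1)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L))
    stop("shape must be three integers, each >= 2")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be three positive reals (mm)")
  b0_direction <- as.numeric(b0_direction)
  if (length(b0_direction) != 3L || any(!is.finite(b0_direction)))
    stop("b0_direction must be a numeric 3-vector")
  if (abs(sqrt(sum(b0_direction^2)) - 1) > 1e-9)
    stop("b0_direction must be a unit vector (|b0| = 1 within 1e-9)")
  structure(list(shape = shape, voxel_size = voxel_size,
                 b0_direction = b0_direction),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d x %d voxels, %.3g x %.3g x %.3g mm, b0 = (%.3g, %.3g, %.3g)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$b0_direction[1], x$b0_direction[2], x$b0_direction[3]))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size, tolerance = 1e-9))
}

check_volume_data <- function(data, geometry, what) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop(what, " data must be a 3-D array")
  if (!identical(as.integer(dim(data)), geometry$shape))
    stop(what, " data shape does not match geometry shape")
  if (!all(is.finite(data)))
    stop(what, " data contains non-finite values")
  invisible(TRUE)
}

#' Susceptibility volume (chi, ppm)
#'
#' @param data real 3-D array of susceptibility values in ppm.
#' @param geometry a [grid_geometry()].
#' @return an object of class `susceptibility_volume`.
#' @export
susceptibility_volume <- function(data, geometry) {
  check_volume_data(data, geometry, "susceptibility")
  structure(list(data = data, geometry = geometry),
            class = "susceptibility_volume")
}

#' Local field volume (normalized field shift, ppm)
#'
#' @param data real 3-D array of the normalized field shift deltaB/B0 in ppm.
#' @param geometry a [grid_geometry()].
#' @return an object of class `field_volume`.
#' @export
field_volume <- function(data, geometry) {
  check_volume_data(data, geometry, "field")
  structure(list(data = data, geometry = geometry), class = "field_volume")
}

#' Volume-of-interest mask
#'
#' The VOI (typically the brain mask) within which signal, pooling, losses
#' and metrics are defined.
#'
#' @param data logical 3-D array; must contain at least one `TRUE` voxel.
#' @param geometry a [grid_geometry()].
#' @return an object of class `voi_mask`.
#' @export
voi_mask <- function(data, geometry) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask data must be a 3-D array")
  data <- array(as.logical(data), dim = dim(data))
  if (!identical(as.integer(dim(data)), geometry$shape))
    stop("mask shape does not match geometry shape")
  if (anyNA(data)) stop("mask contains NA")
  if (!any(data)) stop("mask must contain at least one TRUE voxel")
  structure(list(data = data, geometry = geometry), class = "voi_mask")
}
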
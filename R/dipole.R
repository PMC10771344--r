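#' Discrete Fourier frequencies along one axis
#'
#' Unshifted layout (DC at index 1), in cycles/mm: j/(n*dx) for
#' j = 0, 1, ..., with the upper half wrapped to negative frequencies.
#' Only the direction of k matters for the dipole kernel, so the overall
#' frequency scale cancels; the physical units are kept for clarity.
#'
#' @param n number of samples along the axis.
#' @param dx voxel size along the axis (mm).
#' @return numeric vector of length `n`.
#' @keywords internal
fft_freq <- function(n, dx = 1) {
  j <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  j / (n * dx)
}

#' Build the k-space dipole kernel
#'
#' The unit magnetic dipole acts in k-space as pointwise multiplication by
#' D(k) = 1/3 - (k . b0)^2 / |k|^2, where b0 is the unit B0 direction.
#' With B0 along +z this reduces to the familiar 1/3 - kz^2/k^2. The
#' kernel vanishes on a double cone at the magic angle (~54.7 degrees)
#' around B0, which is what makes single-orientation inversion ill-posed.
#'
#' D is undefined at k = 0; the DC bin is set to `dc_convention`
#' (default 0: the mean susceptibility is unobservable from the local
#' field, so it is conventionally dropped).
#'
#' On even-sized grids the Nyquist frequency is aliased with its negative,
#' so for a tilted B0 axis the raw formula is ambiguous on the Nyquist
#' planes (+1/2 and -1/2 cycles/voxel are the same bin). The kernel is
#' therefore symmetrized over the lattice involution k -> -k, which keeps
#' the forward operator real and exactly even: D(k) = D(-k) everywhere.
#'
#' @param geometry a [grid_geometry()]; the B0 axis is taken from it.
#' @param dc_convention value assigned at the zero-frequency bin.
#' @return an object of class `dipole_kernel` with fields `values`
#'   (3-D array, unshifted FFT layout), `geometry` and `dc_convention`.
#' @export
build_dipole_kernel <- function(geometry, dc_convention = 0) {
  stopifnot(inherits(geometry, "grid_geometry"))
  kx <- fft_freq(geometry$shape[1], geometry$voxel_size[1])
  ky <- fft_freq(geometry$shape[2], geometry$voxel_size[2])
  kz <- fft_freq(geometry$shape[3], geometry$voxel_size[3])
  b <- geometry$b0_direction
  KX <- array(kx, geometry$shape)
  KY <- array(rep(ky, each = geometry$shape[1]), geometry$shape)
  KZ <- array(rep(kz, each = geometry$shape[1] * geometry$shape[2]),
              geometry$shape)
  k2 <- KX^2 + KY^2 + KZ^2
  kb <- KX * b[1] + KY * b[2] + KZ * b[3]
  d <- 1 / 3 - kb^2 / k2
  d[1, 1, 1] <- dc_convention
  # average with the k -> -k image (index j maps to n - j + 2, DC fixed)
  neg <- lapply(geometry$shape, function(n) c(1L, seq.int(n, 2L)))
  d <- (d + d[neg[[1]], neg[[2]], neg[[3]]]) / 2
  # clamp 1-ulp excursions (1/3 - 1 is not exactly -2/3 in binary)
  d <- pmin(pmax(d, -2 / 3), 1 / 3)
  dim(d) <- geometry$shape
  structure(list(values = d, geometry = geometry,
                 dc_convention = dc_convention),
            class = "dipole_kernel")
}

#' Magic angle of the dipole kernel
#'
#' The polar angle (in degrees from B0) at which the dipole kernel
#' vanishes, i.e. the root of 1/3 - cos^2(theta). Returned rounded to one
#' decimal as conventionally quoted (54.7 degrees).
#'
#' @param digits decimal places to round to (default 1).
#' @return angle in degrees.
#' @export
magic_angle_deg <- function(digits = 1) {
  round(acos(sqrt(1 / 3)) * 180 / pi, digits)
}

#' Real-space unit dipole response
#'
#' The z-component (along B0) of the field of a unit point dipole,
#' d(r) = (3 cos^2 theta - 1) / (4 pi |r|^3), with theta the angle between
#' the offset r and the B0 direction. Serves as the real-space oracle for
#' the FFT forward model.
#'
#' @param offset real 3-vector from source to observation point (mm);
#'   must be nonzero.
#' @param b0_direction unit 3-vector.
#' @return dimensionless scalar response.
#' @export
dipole_real_space <- function(offset, b0_direction = c(0, 0, 1)) {
  offset <- as.numeric(offset)
  r <- sqrt(sum(offset^2))
  if (r == 0) stop("dipole response is singular at zero offset")
  b <- as.numeric(b0_direction)
  if (abs(sqrt(sum(b^2)) - 1) > 1e-9)
    stop("b0_direction must be a unit vector")
  cos2 <- (sum(offset * b) / r)^2
  (3 * cos2 - 1) / (4 * pi * r^3)
}

fft3 <- function(x) stats::fft(x)
ifft3 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Forward susceptibility-to-field model
#'
#' Computes the normalized local field shift induced by a susceptibility
#' distribution: deltaB = IFFT( D(k) * FFT(chi) ). The convolution is
#' periodic (pure FFT, no padding); with the DC bin zeroed a constant
#' susceptibility produces zero field.
#'
#' With `pad = TRUE` the volume is zero-padded to twice its size before
#' the FFT and the result cropped back, which suppresses wrap-around and
#' brings the periodic convolution closer to the free-space field of a
#' compact source; off by default, matching the plain pointwise k-space
#' product.
#'
#' @param chi a [susceptibility_volume()] in ppm.
#' @param kernel a [build_dipole_kernel()] result on the same grid.
#' @param pad zero-pad 2x before the FFT (default FALSE).
#' @return a [field_volume()] in ppm.
#' @export
forward_field <- function(chi, kernel, pad = FALSE) {
  stopifnot(inherits(chi, "susceptibility_volume"),
            inherits(kernel, "dipole_kernel"))
  if (!same_grid(chi$geometry, kernel$geometry))
    stop("chi and kernel geometries differ")
  if (pad) {
    g <- chi$geometry
    g2 <- grid_geometry(2L * g$shape, g$voxel_size, g$b0_direction)
    k2 <- build_dipole_kernel(g2, kernel$dc_convention)
    big <- array(0, g2$shape)
    big[seq_len(g$shape[1]), seq_len(g$shape[2]), seq_len(g$shape[3])] <-
      chi$data
    f <- Re(ifft3(k2$values * fft3(big)))
    return(field_volume(f[seq_len(g$shape[1]), seq_len(g$shape[2]),
                          seq_len(g$shape[3])], g))
  }
  f <- ifft3(kernel$values * fft3(chi$data))
  field_volume(Re(f), chi$geometry)
}

#' COSMOS multi-orientation inversion
#'
#' Least-squares combination of local field maps acquired at two or more
#' B0 orientations. Because every dipole kernel is diagonal in k-space,
#' the normal equations decouple per frequency bin and the minimizer is
#' closed-form:
#'   chi(k) = sum_i D_i(k) dB_i(k) / sum_i D_i(k)^2,
#' set to 0 where the denominator falls below `denom_floor` (with well
#' spread orientations only a negligible set of bins is ill-conditioned).
#' `max_iter` and `tol` bound an equivalent iterative normal-equation
#' solve; with the decoupled exact solution they are recorded in the
#' result but never limit accuracy.
#'
#' @param fields list of [field_volume()] objects, one per orientation.
#' @param kernels list of matching [build_dipole_kernel()] results built
#'   with each orientation's B0 direction.
#' @param max_iter iteration budget (default 200).
#' @param tol convergence tolerance (default 1e-5).
#' @param denom_floor bins with sum of squared kernels below this are
#'   zeroed (default 1e-6).
#' @return a [susceptibility_volume()].
#' @export
cosmos_invert <- function(fields, kernels, max_iter = 200, tol = 1e-5,
                          denom_floor = 1e-6) {
  if (length(fields) < 2L) stop("COSMOS needs at least 2 orientations")
  if (length(fields) != length(kernels))
    stop("fields and kernels must pair up")
  g <- fields[[1]]$geometry
  for (i in seq_along(fields)) {
    stopifnot(inherits(fields[[i]], "field_volume"),
              inherits(kernels[[i]], "dipole_kernel"))
    if (!same_grid(fields[[i]]$geometry, g) ||
        !same_grid(kernels[[i]]$geometry, g))
      stop("all orientations must share one grid")
  }
  num <- array(0 + 0i, g$shape)
  den <- array(0, g$shape)
  for (i in seq_along(fields)) {
    d <- kernels[[i]]$values
    num <- num + d * fft3(fields[[i]]$data)
    den <- den + d^2
  }
  chik <- array(0 + 0i, g$shape)
  ok <- den >= denom_floor
  chik[ok] <- num[ok] / den[ok]
  susceptibility_volume(Re(ifft3(chik)), g)
}
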
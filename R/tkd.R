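#' TKD configuration
#'
#' Thresholded k-space division zeroes frequency bins where the dipole
#' kernel magnitude is at or below a threshold T and divides elsewhere.
#' The usual working range for T is 0.15-0.2; the default takes the upper
#' end, trading a little low-frequency content for noise robustness.
#'
#' @param threshold dimensionless kernel-magnitude threshold, in (0, 2/3).
#' @return an object of class `tkd_config`.
#' @export
tkd_config <- function(threshold = 0.2) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0 || threshold >= 2 / 3)
    stop("TKD threshold must lie strictly inside (0, 2/3)")
  structure(list(threshold = threshold), class = "tkd_config")
}

#' Thresholded k-space division
#'
#' Direct dipole inversion chi(k) = deltaB(k) / D(k) on bins with
#' |D(k)| > T, zero elsewhere (bins at |D| = T are zeroed too: they belong
#' to the ill-conditioned set). The result is the pre-estimated
#' susceptibility chi_int that seeds the modulated network's first block.
#'
#' @param field a [field_volume()].
#' @param kernel a [build_dipole_kernel()] result on the same grid.
#' @param config a [tkd_config()].
#' @param mask optional [voi_mask()]; when supplied the returned volume is
#'   zeroed outside the VOI (the default behaviour when seeding the
#'   network).
#' @return a [susceptibility_volume()].
#' @export
tkd_invert <- function(field, kernel, config = tkd_config(), mask = NULL) {
  stopifnot(inherits(field, "field_volume"),
            inherits(kernel, "dipole_kernel"),
            inherits(config, "tkd_config"))
  if (!same_grid(field$geometry, kernel$geometry))
    stop("field and kernel geometries differ")
  keep <- abs(kernel$values) > config$threshold
  chik <- array(0 + 0i, field$geometry$shape)
  chik[keep] <- fft3(field$data)[keep] / kernel$values[keep]
  chi <- Re(ifft3(chik))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "voi_mask"))
    if (!same_grid(mask$geometry, field$geometry))
      stop("mask geometry differs from field geometry")
    chi[!mask$data] <- 0
  }
  susceptibility_volume(chi, field$geometry)
}

#' Fraction of well-conditioned k-space bins
#'
#' Diagnostic for how much of the spectrum a TKD threshold retains:
#' the fraction of frequency bins with |D(k)| > threshold.
#'
#' @param kernel a [build_dipole_kernel()] result.
#' @param threshold nonnegative kernel-magnitude threshold.
#' @return fraction in [0, 1].
#' @export
wellconditioned_fraction <- function(kernel, threshold) {
  stopifnot(inherits(kernel, "dipole_kernel"))
  if (!is.numeric(threshold) || threshold < 0)
    stop("threshold must be >= 0")
  mean(abs(kernel$values) > threshold)
}
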
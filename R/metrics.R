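# Evaluation metrics over the VOI. All four follow the conventions
# common in QSM reconstruction papers: RMSE and HFEN are normalized
# ratios scaled by 100, PSNR uses the reference's dynamic range within
# the mask, and MSSIM is the mean windowed structural-similarity index
# over VOI voxels. Values are comparable within this implementation.

metric_check <- function(x_hat, x_ref, mask) {
  if (!identical(dim(x_hat), dim(x_ref)) ||
      !identical(dim(x_hat), dim(mask)))
    stop("x_hat, x_ref and mask shapes must match")
  idx <- which(array(as.logical(mask), dim(mask)))
  if (length(idx) == 0L) stop("empty mask")
  idx
}

#' Normalized root-mean-square error (x100)
#'
#' 100 * ||x_hat - x_ref|| / ||x_ref||, both restricted to the VOI.
#'
#' @param x_hat,x_ref 3-D arrays; `x_ref` must be nonzero inside the mask.
#' @param mask logical 3-D VOI mask.
#' @return nonnegative scalar (100 = as wrong as predicting zero).
#' @export
rmse <- function(x_hat, x_ref, mask) {
  idx <- metric_check(x_hat, x_ref, mask)
  den <- sqrt(sum(x_ref[idx]^2))
  if (den == 0) stop("RMSE undefined: reference is zero inside the mask")
  100 * sqrt(sum((x_hat[idx] - x_ref[idx])^2)) / den
}

#' Peak signal-to-noise ratio (dB)
#'
#' 10 log10(peak^2 / MSE) with peak the reference max - min inside the
#' mask and MSE over mask voxels; capped at 120 dB for (numerically)
#' identical inputs.
#'
#' @inheritParams rmse
#' @return PSNR in dB.
#' @export
psnr <- function(x_hat, x_ref, mask) {
  idx <- metric_check(x_hat, x_ref, mask)
  peak <- max(x_ref[idx]) - min(x_ref[idx])
  if (peak <= 0) stop("PSNR undefined: constant reference inside the mask")
  mse <- mean((x_hat[idx] - x_ref[idx])^2)
  if (mse < peak^2 * 1e-12) return(120)
  10 * log10(peak^2 / mse)
}

gauss_kernel3 <- function(sigma, size) {
  h <- (size - 1) / 2
  off <- seq(-h, h)
  X <- array(off, c(size, size, size))
  Y <- array(rep(off, each = size), c(size, size, size))
  Z <- array(rep(off, each = size^2), c(size, size, size))
  g <- exp(-(X^2 + Y^2 + Z^2) / (2 * sigma^2))
  g / sum(g)
}

filt_same <- function(x, k) {
  h <- rep((dim(k)[1] - 1L) %/% 2L, 3)
  xp <- pad_symmetric3(x, h)
  filt3_valid(as.numeric(xp), as.numeric(k),
              as.integer(dim(xp)), as.integer(dim(k)))
}

#' Mean structural similarity index over the VOI
#'
#' Windowed SSIM with a Gaussian window (sigma 1.5, edge 7 voxels by
#' default), dynamic range taken as the reference's range within the
#' mask, averaged over VOI voxels. 1 iff the masked volumes are
#' identical; anticorrelated structure drives it negative.
#'
#' @inheritParams rmse
#' @param window_size odd window edge length (default 7).
#' @param sigma Gaussian window scale (default 1.5).
#' @return value in [-1, 1].
#' @export
mssim <- function(x_hat, x_ref, mask, window_size = 7L, sigma = 1.5) {
  idx <- metric_check(x_hat, x_ref, mask)
  if (any(window_size > dim(x_hat)))
    stop("SSIM window larger than the volume")
  L <- max(x_ref[idx]) - min(x_ref[idx])
  if (L <= 0) L <- max(abs(x_ref[idx]), 1e-12)
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  w <- gauss_kernel3(sigma, window_size)
  mu1 <- filt_same(x_hat, w)
  mu2 <- filt_same(x_ref, w)
  s11 <- filt_same(x_hat^2, w) - mu1^2
  s22 <- filt_same(x_ref^2, w) - mu2^2
  s12 <- filt_same(x_hat * x_ref, w) - mu1 * mu2
  ssim_map <- ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
    ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2))
  mean(ssim_map[idx])
}

#' High-frequency error norm (x100)
#'
#' 100 * ||LoG(x_hat) - LoG(x_ref)|| / ||LoG(x_ref)|| over the VOI,
#' sharing the Laplacian-of-Gaussian kernel with the training loss.
#'
#' @inheritParams rmse
#' @param config a [loss_config()] supplying the LoG kernel.
#' @return nonnegative scalar.
#' @export
hfen <- function(x_hat, x_ref, mask, config = loss_config()) {
  idx <- metric_check(x_hat, x_ref, mask)
  f1 <- log_filter(x_hat, config)
  f2 <- log_filter(x_ref, config)
  den <- sqrt(sum(f2[idx]^2))
  if (den == 0)
    stop("HFEN undefined: filtered reference is zero inside the mask")
  100 * sqrt(sum((f1[idx] - f2[idx])^2)) / den
}

#' Full metric report
#'
#' @inheritParams hfen
#' @return list with `psnr`, `rmse`, `mssim`, `hfen`.
#' @export
metric_report <- function(x_hat, x_ref, mask, config = loss_config()) {
  list(psnr = psnr(x_hat, x_ref, mask),
       rmse = rmse(x_hat, x_ref, mask),
       mssim = mssim(x_hat, x_ref, mask),
       hfen = hfen(x_hat, x_ref, mask, config))
}

#' Per-ROI susceptibility statistics
#'
#' Mean and standard deviation of susceptibility (ppm) within each
#' labelled region of interest, e.g. deep-gray-matter nuclei.
#'
#' @param chi 3-D susceptibility array (ppm) or
#'   [susceptibility_volume()].
#' @param roi_masks named list of logical 3-D masks.
#' @return data.frame with columns `label`, `mean`, `sd`, `n_voxels`;
#'   empty ROIs are skipped with a warning.
#' @export
roi_stats <- function(chi, roi_masks) {
  if (inherits(chi, "susceptibility_volume")) chi <- chi$data
  labs <- names(roi_masks)
  if (is.null(labs)) labs <- paste0("roi", seq_along(roi_masks))
  rows <- list()
  for (i in seq_along(roi_masks)) {
    idx <- which(array(as.logical(roi_masks[[i]]), dim(roi_masks[[i]])))
    if (length(idx) == 0L) {
      warning("ROI '", labs[i], "' is empty; skipped")
      next
    }
    v <- chi[idx]
    rows[[length(rows) + 1L]] <-
      data.frame(label = labs[i], mean = mean(v),
                 sd = if (length(v) > 1L) stats::sd(v) else 0,
                 n_voxels = length(v))
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(label = character(0), mean = numeric(0),
                  sd = numeric(0), n_voxels = integer(0))
}
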
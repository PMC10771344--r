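#' Whole-volume reconstruction by patch blending
#'
#' Runs the network over an overlapping patch grid covering the volume
#' and blends predictions with a separable raised-cosine window, so
#' patch seams are feathered rather than stitched. The TKD pre-estimate
#' is computed once on the full volume and cropped per patch.
#'
#' @param model a trained `lcmnet_model`.
#' @param field a [field_volume()].
#' @param magnitude 3-D magnitude array in [0, 1].
#' @param mask a [voi_mask()].
#' @param patch_size integer triple, multiples of 4 (default 64x64x32,
#'   clamped to the volume shape).
#' @param tkd a [tkd_config()] for the pre-estimate.
#' @return a [susceptibility_volume()].
#' @export
reconstruct_volume <- function(model, field, magnitude, mask,
                               patch_size = c(64L, 64L, 32L),
                               tkd = tkd_config()) {
  stopifnot(inherits(model, "lcmnet_model"),
            inherits(field, "field_volume"), inherits(mask, "voi_mask"))
  shape <- field$geometry$shape
  patch_size <- pmin(as.integer(patch_size), shape)
  patch_size <- (patch_size %/% 4L) * 4L
  if (any(patch_size < 4L)) stop("volume too small for patch inference")
  kernel <- build_dipole_kernel(field$geometry)
  chi_init <- tkd_invert(field, kernel, tkd, mask = mask)
  stride <- pmax(patch_size %/% 2L, 1L)
  sx <- patch_starts(0L, shape[1], patch_size[1], stride[1], shape[1])
  sy <- patch_starts(0L, shape[2], patch_size[2], stride[2], shape[2])
  sz <- patch_starts(0L, shape[3], patch_size[3], stride[3], shape[3])
  win1 <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 0.5) / n) + 1e-3
  w3 <- outer(outer(win1(patch_size[1]), win1(patch_size[2])),
              win1(patch_size[3]))
  dim(w3) <- patch_size
  acc <- array(0, shape)
  wacc <- array(0, shape)
  for (x0 in sx) for (y0 in sy) for (z0 in sz) {
    i <- x0 + seq_len(patch_size[1])
    j <- y0 + seq_len(patch_size[2])
    k <- z0 + seq_len(patch_size[3])
    pred <- lcmnet_forward(model,
                           field$data[i, j, k, drop = FALSE],
                           magnitude[i, j, k, drop = FALSE],
                           chi_init$data[i, j, k, drop = FALSE],
                           mask$data[i, j, k, drop = FALSE])
    acc[i, j, k] <- acc[i, j, k] + pred * w3
    wacc[i, j, k] <- wacc[i, j, k] + w3
  }
  out <- acc / wacc
  out[!mask$data] <- 0
  susceptibility_volume(out, field$geometry)
}
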
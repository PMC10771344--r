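#' LCMnet configuration
#'
#' Architecture hyperparameters of the latent-code modulated network.
#' The network has three data pathways: the local field map feeds an
#' encoder chain whose bottleneck is decoded into per-block latent codes;
#' the VOI-masked magnitude image is fused with the multi-level field
#' features in a cross-fusion block; and the TKD pre-estimated
#' susceptibility (chi_int) enters the modulated convolution module (MCM)
#' as the constant initial input that the chain of modulated blocks
#' refines.
#'
#' @param n_levels number of full-resolution encoder levels (default 3).
#' @param base_channels feature channels per level (default 32).
#' @param n_blocks number of modulated convolution blocks (default 3,
#'   supported 2-5).
#' @param epsilon demodulation stabilizer (> 0).
#' @param no_modulation ablation: replace modulated convolutions by
#'   vanilla convolutions (LCMnet_NoMod).
#' @param no_fusion ablation: remove the cross-fusion block; field
#'   features pass through a same-capacity non-fused path and the
#'   magnitude input is ignored (LCMnet_NoFusion).
#' @param field_as_initial_input ablation: replace chi_int by the field
#'   map as the MCM's initial input (LCMnet_deltaB).
#' @param residual add the initial MCM input to the output head, so the
#'   network learns a correction to its susceptibility pre-estimate.
#' @return an object of class `lcmnet_config`.
#' @export
lcmnet_config <- function(n_levels = 3L, base_channels = 32L,
                          n_blocks = 3L, epsilon = 1e-8,
                          no_modulation = FALSE, no_fusion = FALSE,
                          field_as_initial_input = FALSE,
                          residual = TRUE) {
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2L || n_blocks > 5L)
    stop("n_blocks must be between 2 and 5")
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (n_levels < 1L || base_channels < 1L)
    stop("n_levels and base_channels must be >= 1")
  structure(list(n_levels = as.integer(n_levels),
                 base_channels = as.integer(base_channels),
                 n_blocks = n_blocks, epsilon = epsilon,
                 no_modulation = isTRUE(no_modulation),
                 no_fusion = isTRUE(no_fusion),
                 field_as_initial_input = isTRUE(field_as_initial_input),
                 residual = isTRUE(residual),
                 n_downsamplings = 2L, kernel_size = 3L),
            class = "lcmnet_config")
}

#' Modulate convolution weights with a latent code
#'
#' Scales every weight of input channel c by the latent-code entry l_c:
#' w'[p,q,r,c,o] = l[c] * w[p,q,r,c,o]. The latent code length must equal
#' the number of input channels of the kernel.
#'
#' @param w 5-D weight array (K, K, K, Cin, Cout).
#' @param latent numeric vector of length Cin.
#' @return modulated weight array of the same shape.
#' @export
modulate_weights <- function(w, latent) {
  d <- dim(w)
  if (length(d) != 5L) stop("weights must be a 5-D array")
  if (length(latent) != d[4])
    stop("latent code length (", length(latent),
         ") must equal the kernel's input channel count (", d[4], ")")
  if (!all(is.finite(latent))) stop("latent code must be finite")
  l4 <- array(rep(latent, each = prod(d[1:3])), d[1:4])
  w * array(rep(l4, d[5]), d)
}

#' Demodulate convolution weights
#'
#' Per-output-channel renormalization of modulated weights:
#' w''[,,,,o] = w'[,,,,o] / sqrt(sum(w'[,,,,o]^2) + epsilon), the sum
#' running over the input channels and spatial taps of output channel o.
#' This removes the scale the latent code injected, stabilizing training.
#'
#' @param w_prime 5-D modulated weight array.
#' @param epsilon positive stabilizer guarding the all-zero case.
#' @return demodulated weight array.
#' @export
demodulate_weights <- function(w_prime, epsilon = 1e-8) {
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  d <- dim(w_prime)
  if (length(d) != 5L) stop("weights must be a 5-D array")
  m <- matrix(w_prime, ncol = d[5])
  denom <- sqrt(colSums(m^2) + epsilon)
  array(sweep(m, 2, denom, "/"), d)
}

he_init <- function(dim_w) {
  fan_in <- prod(dim_w[1:4])
  array(stats::rnorm(prod(dim_w), sd = sqrt(2 / fan_in)), dim_w)
}

conv_par <- function(k, cin, cout) {
  list(w = he_init(c(k, k, k, cin, cout)), b = numeric(cout))
}

#' Initialize an LCMnet model
#'
#' Draws all weights from scaled-normal (He) initialization. The output
#' head is zero-initialized so that, with the residual connection, the
#' untrained network reproduces its initial susceptibility input exactly;
#' the latent heads start at code 1 (identity modulation) plus a small
#' learned perturbation.
#'
#' @param config an [lcmnet_config()].
#' @param seed integer RNG seed for the initialization draws.
#' @return an object of class `lcmnet_model` with fields `config` and
#'   `params`.
#' @export
lcmnet_init <- function(config = lcmnet_config(), seed = 1L) {
  stopifnot(inherits(config, "lcmnet_config"))
  set.seed(as.integer(seed))
  B <- config$base_channels
  L <- config$n_levels
  M <- config$n_blocks
  k <- config$kernel_size
  p <- list()
  p$enc <- lapply(seq_len(L), function(l)
    list(c1 = conv_par(k, if (l == 1L) 1L else B, B),
         c2 = conv_par(k, B, B)))
  p$down <- lapply(1:2, function(i) conv_par(k, B, B))
  p$dec <- conv_par(k, B, B)
  p$lat <- lapply(seq_len(M), function(i)
    list(W = matrix(stats::rnorm(B * B, sd = 0.01), B, B),
         b = rep(1, B)))
  if (!config$no_fusion) {
    p$mag <- list(c1 = conv_par(k, 1L, B), c2 = conv_par(k, B, B))
    p$fuse_mix <- list(w = he_init(c(1L, 1L, 1L, (L + 1L) * B, B)),
                       b = numeric(B))
  }
  p$fuse_level <- lapply(seq_len(L), function(l) conv_par(k, B, B))
  p$fuse_out <- lapply(seq_len(L), function(l) conv_par(k, B, B))
  p$stem <- conv_par(k, 1L, B)
  p$blocks <- lapply(seq_len(M), function(i)
    list(mod_w = he_init(c(k, k, k, B, B)), mod_b = numeric(B),
         comb_w = he_init(c(k, k, k, 2L * B, B)), comb_b = numeric(B)))
  p$head <- list(w = array(0, c(k, k, k, B, 1L)), b = numeric(1))
  structure(list(config = config, params = p), class = "lcmnet_model")
}

check_patch_dims <- function(dim3, config) {
  mult <- 2^config$n_downsamplings
  if (any(dim3 %% mult != 0L))
    stop("patch dimensions must be multiples of ", mult,
         " (two downsampling steps); got ", paste(dim3, collapse = "x"))
}

convblock_fwd <- function(x, p) {
  pre <- nn_conv(x, p$w, p$b)
  list(y = nn_lrelu(pre), pre = pre, x = x)
}

convblock_bwd <- function(cb, p, gy) {
  gpre <- nn_lrelu_bwd(cb$pre, gy)
  nn_conv_bwd(cb$x, p$w, gpre)
}

#' Encode the field patch into multi-level features
#'
#' Runs the chain of full-resolution encoder blocks over the field map,
#' returning the per-level feature maps FB1..FBn and the bottleneck Fd
#' produced by two further encoder blocks with factor-2 downsampling.
#'
#' @param model an [lcmnet_init()] model.
#' @param field_patch 3-D field array (ppm); dimensions must be
#'   multiples of 4.
#' @return list with `levels` (list of n feature maps) and `fd`.
#' @export
encode_field <- function(model, field_patch) {
  stopifnot(inherits(model, "lcmnet_model"))
  check_patch_dims(dim(as4d(field_patch))[1:3], model$config)
  fw <- encode_field_fwd(model$params, model$config, as4d(field_patch))
  list(levels = lapply(fw$levels, `[[`, "y2"), fd = fw$fd$y)
}

encode_field_fwd <- function(p, config, x) {
  levels <- vector("list", config$n_levels)
  h <- x
  for (l in seq_len(config$n_levels)) {
    c1 <- convblock_fwd(h, p$enc[[l]]$c1)
    c2 <- convblock_fwd(c1$y, p$enc[[l]]$c2)
    levels[[l]] <- list(c1 = c1, c2 = c2, y2 = c2$y)
    h <- c2$y
  }
  d1in <- nn_avgpool2(h)
  d1 <- convblock_fwd(d1in, p$down[[1]])
  d2in <- nn_avgpool2(d1$y)
  d2 <- convblock_fwd(d2in, p$down[[2]])
  list(levels = levels, d1 = d1, d2 = d2,
       d1in_dim = dim(as4d(h)), d2in_dim = dim(d1$y), fd = d2)
}

#' Decode the bottleneck into per-block latent codes
#'
#' The bottleneck features are zeroed outside the downsampled VOI (the
#' mask is mean-pooled to Fd resolution and thresholded at 0.5), passed
#' through a convolution, pooled by a VOI-restricted global average, and
#' projected by one linear head per modulated block. Because of the entry
#' masking and the restricted pooling, voxels outside the downsampled VOI
#' can never influence the codes.
#'
#' @param model an [lcmnet_init()] model.
#' @param fd bottleneck feature array (X/4, Y/4, Z/4, C).
#' @param mask logical 3-D mask at full patch resolution, or already at
#'   Fd resolution (matching fd's spatial dims).
#' @return list of numeric latent-code vectors, one per modulated block.
#' @export
decode_latent <- function(model, fd, mask) {
  stopifnot(inherits(model, "lcmnet_model"))
  fd <- as4d(fd)
  md <- if (identical(as.integer(dim(mask)), as.integer(dim(fd)[1:3]))) {
    array(as.logical(mask), dim(mask))
  } else {
    downsample_mask(mask, model$config$n_downsamplings)
  }
  if (!any(md))
    stop("VOI mask is empty after downsampling to the bottleneck grid")
  fw <- decode_latent_fwd(model$params, model$config, fd, md)
  fw$latents
}

decode_latent_fwd <- function(p, config, fd, mask_d) {
  fd <- fd * as.numeric(mask_d)   # broadcast over channels
  dec <- convblock_fwd(fd, p$dec)
  v <- nn_masked_gap(dec$y, mask_d)
  latents <- lapply(seq_len(config$n_blocks), function(i)
    as.numeric(p$lat[[i]]$W %*% v + p$lat[[i]]$b))
  list(dec = dec, v = v, latents = latents, mask_d = mask_d)
}

#' Cross-fusion of field and magnitude features
#'
#' The VOI-masked magnitude image passes through a small convolution
#' stack; each field level FBi is processed by a Conv3; the level and
#' magnitude features are concatenated and fused by a Conv1 (1x1x1);
#' per-level Conv3 heads emit the fused maps FBM1..FBMn. Under the
#' `no_fusion` ablation each level passes through the same-capacity
#' Conv3-Conv3 path and the magnitude input is ignored entirely.
#'
#' @param model an [lcmnet_init()] model.
#' @param field_features result of [encode_field()] (or its `levels`).
#' @param magnitude_patch 3-D magnitude array in [0, 1].
#' @param mask logical 3-D VOI mask at patch resolution.
#' @return list of fused feature maps, one per level.
#' @export
cross_fusion <- function(model, field_features, magnitude_patch, mask) {
  stopifnot(inherits(model, "lcmnet_model"))
  levels <- if (!is.null(field_features$levels)) field_features$levels
            else field_features
  fw <- cross_fusion_fwd(model$params, model$config,
                         lapply(levels, as4d),
                         as4d(magnitude_patch * as.numeric(mask)))
  lapply(fw$outs, `[[`, "y")
}

cross_fusion_fwd <- function(p, config, levels, mag_masked) {
  L <- config$n_levels
  gs <- lapply(seq_len(L), function(l)
    convblock_fwd(levels[[l]], p$fuse_level[[l]]))
  if (config$no_fusion) {
    outs <- lapply(seq_len(L), function(l)
      convblock_fwd(gs[[l]]$y, p$fuse_out[[l]]))
    return(list(gs = gs, outs = outs, no_fusion = TRUE))
  }
  m1 <- convblock_fwd(mag_masked, p$mag$c1)
  m2 <- convblock_fwd(m1$y, p$mag$c2)
  cat <- Reduce(nn_concat, c(lapply(gs, `[[`, "y"), list(m2$y)))
  mix <- convblock_fwd(cat, p$fuse_mix)
  outs <- lapply(seq_len(L), function(l)
    convblock_fwd(mix$y, p$fuse_out[[l]]))
  list(gs = gs, m1 = m1, m2 = m2, cat = cat, mix = mix, outs = outs,
       no_fusion = FALSE)
}

#' One modulated convolution block
#'
#' Applies the modulate-demodulate convolution to the incoming
#' susceptibility features, concatenates the result with the fused
#' field/magnitude features, and finishes with a Conv3 and a leaky
#' rectifier. With `config$no_modulation` the modulation and
#' demodulation steps are skipped (vanilla convolution).
#'
#' @param features_in feature array (X, Y, Z, C).
#' @param latent latent-code vector (length C), ignored under
#'   `no_modulation`.
#' @param fused_features fused feature array with matching spatial shape.
#' @param weights list with `mod_w`, `mod_b`, `comb_w`, `comb_b`.
#' @param config an [lcmnet_config()].
#' @return output feature array with `base_channels` channels.
#' @export
modulated_conv_block <- function(features_in, latent, fused_features,
                                 weights, config = lcmnet_config()) {
  features_in <- as4d(features_in)
  fused_features <- as4d(fused_features)
  if (!all(dim(features_in)[1:3] == dim(fused_features)[1:3]))
    stop("features_in and fused_features spatial shapes differ")
  fw <- mod_block_fwd(weights, config, features_in, latent, fused_features)
  fw$h
}

mod_block_fwd <- function(bp, config, x_in, latent, fbm) {
  if (config$no_modulation) {
    w_used <- bp$mod_w
    cache_mod <- NULL
  } else {
    w_prime <- modulate_weights(bp$mod_w, latent)
    d <- dim(w_prime)
    s <- colSums(matrix(w_prime, ncol = d[5])^2)
    denom <- sqrt(s + config$epsilon)
    w_used <- array(sweep(matrix(w_prime, ncol = d[5]), 2, denom, "/"), d)
    cache_mod <- list(w_prime = w_prime, denom = denom)
  }
  u <- nn_conv(x_in, w_used, bp$mod_b)
  cat <- nn_concat(u, fbm)
  pre <- nn_conv(cat, bp$comb_w, bp$comb_b)
  h <- nn_lrelu(pre)
  list(x_in = x_in, latent = latent, w_used = w_used, cache_mod = cache_mod,
       u = u, cat = cat, pre = pre, h = h)
}

mod_block_bwd <- function(bp, config, cache, gh) {
  gpre <- nn_lrelu_bwd(cache$pre, gh)
  comb <- nn_conv_bwd(cache$cat, bp$comb_w, gpre)
  sp <- nn_split(comb$gx, dim(cache$u)[4])
  gu <- sp[[1]]; gfbm <- sp[[2]]
  modc <- nn_conv_bwd(cache$x_in, cache$w_used, gu)
  gw_used <- modc$gw
  if (config$no_modulation) {
    gmod_w <- gw_used
    glat <- numeric(length(cache$latent))
  } else {
    d <- dim(bp$mod_w)
    wP <- matrix(cache$cache_mod$w_prime, ncol = d[5])
    gU <- matrix(gw_used, ncol = d[5])
    denom <- cache$cache_mod$denom
    dots <- colSums(gU * wP)
    gP <- sweep(gU, 2, denom, "/") -
      sweep(wP, 2, dots / denom^3, "*")
    gP <- array(gP, d)
    l4 <- array(rep(array(rep(cache$latent, each = prod(d[1:3])), d[1:4]),
                    d[5]), d)
    gmod_w <- gP * l4
    glat <- apply(bp$mod_w * gP, 4, sum)
  }
  list(gx_in = modc$gx, gfbm = gfbm, glat = glat,
       g = list(mod_w = gmod_w, mod_b = modc$gb,
                comb_w = comb$gw, comb_b = comb$gb))
}

#' LCMnet forward pass
#'
#' Full reconstruction of one patch: field encoding, latent-code
#' decoding, cross-fusion with the magnitude image, and the chain of
#' modulated convolution blocks starting from the pre-estimated
#' susceptibility, finished by the output head (plus the residual
#' connection from the initial input when configured). All inputs are
#' multiplied by the VOI mask on entry, so values outside the VOI never
#' influence the output.
#'
#' @param model an [lcmnet_init()] model.
#' @param field_patch,magnitude_patch,chi_init_patch 3-D arrays sharing
#'   one shape (dimensions multiples of 4).
#' @param mask_patch logical 3-D VOI mask of the same shape.
#' @return reconstructed susceptibility patch (3-D array, ppm).
#' @export
lcmnet_forward <- function(model, field_patch, magnitude_patch,
                           chi_init_patch, mask_patch) {
  fw <- lcmnet_fwd(model, field_patch, magnitude_patch, chi_init_patch,
                   mask_patch)
  fw$out
}

lcmnet_fwd <- function(model, field_patch, magnitude_patch,
                       chi_init_patch, mask_patch) {
  stopifnot(inherits(model, "lcmnet_model"))
  config <- model$config
  p <- model$params
  dims <- dim(as4d(field_patch))[1:3]
  for (a in list(magnitude_patch, chi_init_patch, mask_patch))
    if (!all(dim(as4d(a))[1:3] == dims))
      stop("all input patches must share one spatial shape")
  check_patch_dims(dims, config)
  m <- as.numeric(mask_patch)
  field <- as4d(array(field_patch * m, dims))
  mag <- as4d(array(magnitude_patch * m, dims))
  chi0 <- as4d(array(chi_init_patch * m, dims))
  x0 <- if (config$field_as_initial_input) field else chi0

  enc <- encode_field_fwd(p, config, field)
  mask_d <- downsample_mask(array(as.logical(mask_patch), dims),
                            config$n_downsamplings)
  if (!any(mask_d))
    stop("VOI mask is empty after downsampling to the bottleneck grid")
  lat <- decode_latent_fwd(p, config, enc$fd$y, mask_d)
  fus <- cross_fusion_fwd(p, config, lapply(enc$levels, `[[`, "y2"), mag)

  stem <- convblock_fwd(x0, p$stem)
  h <- stem$y
  blocks <- vector("list", config$n_blocks)
  for (i in seq_len(config$n_blocks)) {
    li <- min(i, config$n_levels)
    blocks[[i]] <- mod_block_fwd(p$blocks[[i]], config, h,
                                 lat$latents[[i]], fus$outs[[li]]$y)
    h <- blocks[[i]]$h
  }
  head_y <- nn_conv(h, p$head$w, p$head$b)
  out <- head_y[, , , 1]
  if (config$residual) out <- out + x0[, , , 1]
  list(out = out,
       cache = list(enc = enc, lat = lat, fus = fus, stem = stem,
                    blocks = blocks, h_last = h, x0 = x0, mask = m,
                    dims = dims))
}

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like)
  else if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
  else if (is.array(x)) array(0, dim(x))
  else numeric(length(x))
}

grads_add <- function(a, b) {
  if (is.list(a)) mapply(grads_add, a, b, SIMPLIFY = FALSE)
  else a + b
}

grads_scale <- function(a, s) {
  if (is.list(a)) lapply(a, grads_scale, s = s)
  else a * s
}

# Backward pass: gout is the gradient of the loss w.r.t. the 3-D output.
# Returns gradients in the same nested structure as model$params.
lcmnet_bwd <- function(model, fw, gout) {
  config <- model$config
  p <- model$params
  cc <- fw$cache
  g <- zero_like(p)
  gx0 <- array(0, dim(cc$x0))

  g4 <- array(gout, c(cc$dims, 1L))
  if (config$residual) gx0 <- gx0 + g4
  hr <- nn_conv_bwd(cc$h_last, p$head$w, g4)
  g$head$w <- hr$gw; g$head$b <- hr$gb
  gh <- hr$gx

  glat <- vector("list", config$n_blocks)
  gfbm_acc <- lapply(seq_len(config$n_levels),
                     function(l) NULL)
  for (i in rev(seq_len(config$n_blocks))) {
    bb <- mod_block_bwd(p$blocks[[i]], config, cc$blocks[[i]], gh)
    g$blocks[[i]] <- bb$g
    glat[[i]] <- bb$glat
    li <- min(i, config$n_levels)
    gfbm_acc[[li]] <- if (is.null(gfbm_acc[[li]])) bb$gfbm
                      else gfbm_acc[[li]] + bb$gfbm
    gh <- bb$gx_in
  }
  sr <- convblock_bwd(cc$stem, p$stem, gh)
  g$stem$w <- sr$gw; g$stem$b <- sr$gb
  gx0 <- gx0 + sr$gx

  # cross-fusion backward
  fus <- cc$fus
  L <- config$n_levels
  glevels <- vector("list", L)
  gmag <- NULL
  if (fus$no_fusion) {
    for (l in seq_len(L)) {
      gfl <- if (is.null(gfbm_acc[[l]]))
        array(0, dim(fus$outs[[l]]$y)) else gfbm_acc[[l]]
      outr <- convblock_bwd(fus$outs[[l]], p$fuse_out[[l]], gfl)
      g$fuse_out[[l]]$w <- outr$gw; g$fuse_out[[l]]$b <- outr$gb
      gr <- convblock_bwd(fus$gs[[l]], p$fuse_level[[l]], outr$gx)
      g$fuse_level[[l]]$w <- gr$gw; g$fuse_level[[l]]$b <- gr$gb
      glevels[[l]] <- gr$gx
    }
  } else {
    gmix <- array(0, dim(fus$mix$y))
    for (l in seq_len(L)) {
      gfl <- if (is.null(gfbm_acc[[l]]))
        array(0, dim(fus$outs[[l]]$y)) else gfbm_acc[[l]]
      outr <- convblock_bwd(fus$outs[[l]], p$fuse_out[[l]], gfl)
      g$fuse_out[[l]]$w <- outr$gw; g$fuse_out[[l]]$b <- outr$gb
      gmix <- gmix + outr$gx
    }
    mixr <- convblock_bwd(fus$mix, p$fuse_mix, gmix)
    g$fuse_mix$w <- mixr$gw; g$fuse_mix$b <- mixr$gb
    B <- config$base_channels
    gcat <- mixr$gx
    for (l in seq_len(L)) {
      sp <- nn_split(gcat, B)
      gcat_l <- sp[[1]]; gcat <- sp[[2]]
      gr <- convblock_bwd(fus$gs[[l]], p$fuse_level[[l]], gcat_l)
      g$fuse_level[[l]]$w <- gr$gw; g$fuse_level[[l]]$b <- gr$gb
      glevels[[l]] <- gr$gx
    }
    gm2 <- gcat
    m2r <- convblock_bwd(fus$m2, p$mag$c2, gm2)
    g$mag$c2$w <- m2r$gw; g$mag$c2$b <- m2r$gb
    m1r <- convblock_bwd(fus$m1, p$mag$c1, m2r$gx)
    g$mag$c1$w <- m1r$gw; g$mag$c1$b <- m1r$gb
    gmag <- m1r$gx
  }

  # latent decoder backward
  lat <- cc$lat
  gv <- numeric(length(lat$v))
  for (i in seq_len(config$n_blocks)) {
    g$lat[[i]]$W <- glat[[i]] %o% lat$v
    g$lat[[i]]$b <- glat[[i]]
    gv <- gv + as.numeric(crossprod(p$lat[[i]]$W, glat[[i]]))
  }
  gdec_y <- nn_masked_gap_bwd(dim(lat$dec$y), lat$mask_d, gv)
  decr <- convblock_bwd(lat$dec, p$dec, gdec_y)
  g$dec$w <- decr$gw; g$dec$b <- decr$gb
  gfd <- decr$gx * as.numeric(lat$mask_d)  # entry masking of the decoder

  # encoder backward (down path then level chain)
  enc <- cc$enc
  d2r <- convblock_bwd(enc$d2, p$down[[2]], gfd)
  g$down[[2]]$w <- d2r$gw; g$down[[2]]$b <- d2r$gb
  gd1y <- nn_avgpool2_bwd(enc$d2in_dim, d2r$gx)
  d1r <- convblock_bwd(enc$d1, p$down[[1]], gd1y)
  g$down[[1]]$w <- d1r$gw; g$down[[1]]$b <- d1r$gb
  ghl <- nn_avgpool2_bwd(enc$d1in_dim, d1r$gx)

  for (l in rev(seq_len(L))) {
    gy2 <- ghl + glevels[[l]]
    c2r <- convblock_bwd(enc$levels[[l]]$c2, p$enc[[l]]$c2, gy2)
    g$enc[[l]]$c2$w <- c2r$gw; g$enc[[l]]$c2$b <- c2r$gb
    c1r <- convblock_bwd(enc$levels[[l]]$c1, p$enc[[l]]$c1, c2r$gx)
    g$enc[[l]]$c1$w <- c1r$gw; g$enc[[l]]$c1$b <- c1r$gb
    ghl <- c1r$gx
  }
  g
}
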
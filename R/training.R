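#' Loss configuration
#'
#' The training loss combines a masked mean-squared (Frobenius) term with
#' a high-frequency error term computed after Laplacian-of-Gaussian (LoG)
#' filtering, weighted by `alpha`. The discrete LoG kernel is built from
#' the analytic 3-D LoG truncated to `log_kernel_size` voxels and
#' mean-subtracted so it sums to exactly zero (constants are annihilated
#' exactly).
#'
#' @param alpha weight of the high-frequency term (>= 0, default 0.1; not
#'   prescribed by the training protocol the package follows — see the
#'   methods vignette).
#' @param log_sigma Gaussian scale of the LoG kernel in voxels
#'   (default 1.5).
#' @param log_kernel_size odd kernel edge length >= 3 (default 9).
#' @return an object of class `loss_config` carrying the prebuilt kernel.
#' @export
loss_config <- function(alpha = 0.1, log_sigma = 1.5, log_kernel_size = 9L) {
  if (!is.numeric(alpha) || alpha < 0) stop("alpha must be >= 0")
  if (!is.numeric(log_sigma) || log_sigma <= 0)
    stop("log_sigma must be > 0")
  log_kernel_size <- as.integer(log_kernel_size)
  if (log_kernel_size < 3L || log_kernel_size %% 2L == 0L)
    stop("log_kernel_size must be an odd integer >= 3")
  structure(list(alpha = alpha, log_sigma = log_sigma,
                 log_kernel_size = log_kernel_size,
                 kernel = log_kernel(log_sigma, log_kernel_size)),
            class = "loss_config")
}

#' Discrete Laplacian-of-Gaussian kernel
#'
#' Analytic 3-D LoG, (r^2 - 3 sigma^2)/sigma^4 times the normalized
#' Gaussian, sampled at integer offsets and mean-subtracted to sum to
#' exactly zero.
#'
#' @param sigma Gaussian scale (voxels).
#' @param size odd kernel edge length.
#' @return 3-D array of size `size`^3.
#' @export
log_kernel <- function(sigma, size) {
  h <- (size - 1) / 2
  off <- seq(-h, h)
  X <- array(off, c(size, size, size))
  Y <- array(rep(off, each = size), c(size, size, size))
  Z <- array(rep(off, each = size^2), c(size, size, size))
  r2 <- X^2 + Y^2 + Z^2
  g <- exp(-r2 / (2 * sigma^2)) / (2 * pi * sigma^2)^1.5
  k <- (r2 - 3 * sigma^2) / sigma^4 * g
  k - mean(k)
}

pad_symmetric3 <- function(x, h) {
  d <- dim(x)
  if (any(h > d)) stop("padding exceeds volume size")
  ix <- c(h[1]:1, seq_len(d[1]), d[1]:(d[1] - h[1] + 1))
  iy <- c(h[2]:1, seq_len(d[2]), d[2]:(d[2] - h[2] + 1))
  iz <- c(h[3]:1, seq_len(d[3]), d[3]:(d[3] - h[3] + 1))
  x[ix, iy, iz, drop = FALSE]
}

#' Laplacian-of-Gaussian filtering
#'
#' Linear shift-invariant filtering with the loss kernel under symmetric
#' boundary padding; output shape equals input shape.
#'
#' @param volume real 3-D array.
#' @param config a [loss_config()].
#' @return filtered 3-D array.
#' @export
log_filter <- function(volume, config = loss_config()) {
  stopifnot(inherits(config, "loss_config"))
  if (length(dim(volume)) != 3L) stop("volume must be 3-D")
  k <- config$kernel
  h <- rep((dim(k)[1] - 1L) %/% 2L, 3)
  xp <- pad_symmetric3(volume, h)
  filt3_valid(as.numeric(xp), as.numeric(k),
              as.integer(dim(xp)), as.integer(dim(k)))
}

zeropad3 <- function(x, h) {
  d <- dim(x)
  out <- array(0, d + 2 * h)
  out[(h[1] + 1):(h[1] + d[1]), (h[2] + 1):(h[2] + d[2]),
      (h[3] + 1):(h[3] + d[3])] <- x
  out
}

# adjoint of log_filter (kernel is even-symmetric, so only the padding
# adjoint differs from the forward filter)
log_filter_adjoint <- function(g, config) {
  k <- config$kernel
  s <- dim(k)[1]
  h <- rep((s - 1L) %/% 2L, 3)
  gp <- zeropad3(g, rep(s - 1L, 3))
  full <- filt3_valid(as.numeric(gp), as.numeric(k),
                      as.integer(dim(gp)), as.integer(dim(k)))
  fold_symmetric3_all(full, h, dim(g))
}

# full three-axis fold of symmetric padding
fold_symmetric3_all <- function(g, h, out_dim) {
  res <- g
  for (axis in 1:3) {
    d <- dim(res)
    n <- out_dim[axis]; hh <- h[axis]
    take <- function(r) switch(axis,
      res[r, , , drop = FALSE], res[, r, , drop = FALSE],
      res[, , r, drop = FALSE])
    core <- take((hh + 1):(hh + n))
    if (hh > 0) {
      left <- take(hh:1)
      right <- take((hh + n + 1):d[axis])
      addin <- function(core, blk, pos) {
        if (axis == 1) core[pos, , ] <- core[pos, , , drop = FALSE] + blk
        else if (axis == 2) core[, pos, ] <- core[, pos, , drop = FALSE] + blk
        else core[, , pos] <- core[, , pos, drop = FALSE] + blk
        core
      }
      core <- addin(core, left, seq_len(hh))
      core <- addin(core, right, n:(n - hh + 1))
    }
    res <- core
  }
  res
}

#' Training loss: masked MSE plus HFEN term
#'
#' loss = || m (chi_hat - chi_ref) ||_F^2
#'      + alpha * || m (LoG(m chi_hat) - LoG(m chi_ref)) ||_F^2
#' with m the VOI indicator. Both volumes are zeroed outside the VOI
#' before filtering and both terms again before the norm, so the loss is
#' zero exactly when the masked volumes coincide and voxels outside the
#' VOI can never contribute.
#'
#' @param chi_hat,chi_ref 3-D arrays of matching shape (ppm).
#' @param mask logical 3-D VOI mask of the same shape.
#' @param config a [loss_config()].
#' @return nonnegative scalar; zero iff the masked volumes coincide.
#' @export
training_loss <- function(chi_hat, chi_ref, mask, config = loss_config()) {
  training_loss_grad(chi_hat, chi_ref, mask, config, want_grad = FALSE)$loss
}

#' Training loss with its analytic gradient
#'
#' @inheritParams training_loss
#' @param want_grad compute the gradient with respect to `chi_hat`.
#' @return list with `loss` and (optionally) `grad`, a 3-D array.
#' @export
training_loss_grad <- function(chi_hat, chi_ref, mask,
                               config = loss_config(), want_grad = TRUE) {
  if (!identical(dim(chi_hat), dim(chi_ref)) ||
      !identical(dim(chi_hat), dim(mask)))
    stop("chi_hat, chi_ref and mask shapes must match")
  stopifnot(inherits(config, "loss_config"))
  m <- array(as.numeric(mask), dim(mask))
  d0 <- m * (chi_hat - chi_ref)
  loss <- sum(d0^2)
  grad <- if (want_grad) 2 * d0 else NULL
  if (config$alpha > 0) {
    df <- m * (log_filter(m * chi_hat, config) -
               log_filter(m * chi_ref, config))
    loss <- loss + config$alpha * sum(df^2)
    if (want_grad)
      grad <- grad +
        2 * config$alpha * m * log_filter_adjoint(m * df, config)
  }
  list(loss = loss, grad = grad)
}

#' Training configuration
#'
#' Optimization hyperparameters for patch-based training: decoupled
#' weight decay (AdamW) with weight decay 5e-4, initial learning rate
#' 1e-4 and 30 epochs by default; patches of 64 x 64 x 32.
#'
#' @param learning_rate AdamW step size (default 1e-4).
#' @param weight_decay decoupled weight decay (default 5e-4).
#' @param epochs training epochs (default 30).
#' @param patch_size integer triple (default 64 x 64 x 32).
#' @param batch_size patches per optimization step (default 4).
#' @param max_steps optional cap on total optimization steps.
#' @param seed RNG seed for shuffling.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 5e-4,
                         epochs = 30L, patch_size = c(64L, 64L, 32L),
                         batch_size = 4L, max_steps = Inf, seed = 1L) {
  if (learning_rate < 0 || weight_decay < 0)
    stop("learning_rate and weight_decay must be >= 0")
  if (epochs < 1L || batch_size < 1L)
    stop("epochs and batch_size must be >= 1")
  structure(list(learning_rate = learning_rate,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 max_steps = max_steps, seed = as.integer(seed)),
            class = "train_config")
}

adamw_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adamw_update <- function(params, grads, state, lr, wd,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(upd, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * (mhat / (sqrt(vhat) + eps) + wd * p)
    list(p = p, m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

#' Assemble aligned training patches
#'
#' Computes the TKD pre-estimate chi_int per volume (masked by the VOI)
#' and crops the dataset's patch grid into aligned
#' (field, magnitude, chi_init, mask, chi_ref) records. Inputs stay in
#' physical ppm units; no per-volume normalization is applied.
#'
#' @param dataset result of [build_dataset()].
#' @param tkd a [tkd_config()] used for the pre-estimate.
#' @return list of patch records.
#' @export
prepare_patches <- function(dataset, tkd = tkd_config()) {
  kernel <- build_dipole_kernel(dataset$samples[[1]]$chi$geometry)
  chi_inits <- lapply(dataset$samples, function(s)
    tkd_invert(s$field, kernel, tkd, mask = s$mask))
  lapply(seq_len(nrow(dataset$patches)), function(r) {
    rec <- dataset$patches[r, ]
    si <- rec$sample
    corner <- c(rec$x0, rec$y0, rec$z0)
    pp <- extract_patch(dataset$samples[[si]], corner, dataset$patch_size)
    i <- corner[1] + seq_len(dataset$patch_size[1])
    j <- corner[2] + seq_len(dataset$patch_size[2])
    k <- corner[3] + seq_len(dataset$patch_size[3])
    pp$chi_init <- chi_inits[[si]]$data[i, j, k, drop = FALSE]
    pp
  })
}

#' Train an LCMnet model
#'
#' Patch-based optimization of the masked MSE + HFEN loss with AdamW
#' (decoupled weight decay). Patches are shuffled each epoch under the
#' configured seed; the per-epoch mean loss is recorded. Training aborts
#' with a diagnostic if the loss becomes non-finite.
#'
#' @param model an [lcmnet_init()] model.
#' @param patches list of patch records from [prepare_patches()].
#' @param tconf a [train_config()].
#' @param lconf a [loss_config()].
#' @return list with `model` (trained), `history` (per-epoch mean loss)
#'   and `step_losses`.
#' @export
train <- function(model, patches, tconf = train_config(),
                  lconf = loss_config()) {
  stopifnot(inherits(model, "lcmnet_model"),
            inherits(tconf, "train_config"),
            inherits(lconf, "loss_config"))
  if (length(patches) == 0L) stop("empty training dataset")
  set.seed(tconf$seed)
  state <- adamw_init(model$params)
  history <- numeric(0)
  step_losses <- numeric(0)
  step <- 0L
  for (epoch in seq_len(tconf$epochs)) {
    ord <- sample.int(length(patches))
    epoch_losses <- numeric(0)
    b <- 1L
    while (b <= length(ord)) {
      sel <- ord[b:min(b + tconf$batch_size - 1L, length(ord))]
      b <- b + tconf$batch_size
      gacc <- NULL
      lsum <- 0
      for (s in sel) {
        pp <- patches[[s]]
        fw <- lcmnet_fwd(model, pp$field, pp$magnitude, pp$chi_init,
                         pp$mask)
        lg <- training_loss_grad(fw$out, array(pp$chi, dim(fw$out)),
                                 array(pp$mask, dim(fw$out)), lconf)
        if (!is.finite(lg$loss))
          stop("non-finite loss at step ", step + 1L,
               "; inspect inputs or lower the learning rate")
        g <- lcmnet_bwd(model, fw, lg$grad)
        gacc <- if (is.null(gacc)) g else grads_add(gacc, g)
        lsum <- lsum + lg$loss
      }
      gacc <- grads_scale(gacc, 1 / length(sel))
      up <- adamw_update(model$params, gacc, state,
                         tconf$learning_rate, tconf$weight_decay)
      model$params <- up$params
      state <- up$state
      step <- step + 1L
      epoch_losses <- c(epoch_losses, lsum / length(sel))
      step_losses <- c(step_losses, lsum / length(sel))
      if (step >= tconf$max_steps) break
    }
    history <- c(history, mean(epoch_losses))
    if (step >= tconf$max_steps) break
  }
  list(model = model, history = history, step_losses = step_losses)
}

variant_config <- function(base, variant) {
  cfg <- base
  switch(variant,
         LCMnet = cfg,
         LCMnet_NoMod = { cfg$no_modulation <- TRUE; cfg },
         LCMnet_NoFusion = { cfg$no_fusion <- TRUE; cfg },
         LCMnet_deltaB = { cfg$field_as_initial_input <- TRUE; cfg },
         stop("unknown variant: ", variant))
}

#' Ablation harness
#'
#' Trains the full model and its three ablation variants (vanilla
#' convolutions in place of modulated ones; cross-fusion removed; the
#' field map in place of the TKD pre-estimate) under identical data,
#' seeds and budgets, then scores each on held-out patches.
#'
#' @param train_patches,holdout_patches patch-record lists from
#'   [prepare_patches()].
#' @param base_config an [lcmnet_config()] for the full model.
#' @param tconf a [train_config()].
#' @param lconf a [loss_config()].
#' @param variants character vector of variant names.
#' @param init_seed seed for weight initialization (shared).
#' @return list with `table` (one row per variant: epoch-1 and final
#'   mean loss, held-out PSNR/RMSE/MSSIM/HFEN) and `histories`.
#' @export
run_ablation_suite <- function(train_patches, holdout_patches,
                               base_config = lcmnet_config(),
                               tconf = train_config(),
                               lconf = loss_config(),
                               variants = c("LCMnet", "LCMnet_NoMod",
                                            "LCMnet_NoFusion",
                                            "LCMnet_deltaB"),
                               init_seed = 1L) {
  rows <- list()
  histories <- list()
  for (v in variants) {
    cfg <- variant_config(base_config, v)
    model <- lcmnet_init(cfg, seed = init_seed)
    tr <- train(model, train_patches, tconf, lconf)
    preds <- lapply(holdout_patches, function(pp)
      lcmnet_forward(tr$model, pp$field, pp$magnitude, pp$chi_init,
                     pp$mask))
    sc <- vapply(seq_along(holdout_patches), function(i) {
      pp <- holdout_patches[[i]]
      c(psnr = psnr(preds[[i]], pp$chi, pp$mask),
        rmse = rmse(preds[[i]], pp$chi, pp$mask),
        mssim = mssim(preds[[i]], pp$chi, pp$mask),
        hfen = hfen(preds[[i]], pp$chi, pp$mask, lconf))
    }, numeric(4))
    rows[[v]] <- data.frame(variant = v,
                            epoch1_loss = tr$history[1],
                            final_loss = tr$history[length(tr$history)],
                            psnr = mean(sc["psnr", ]),
                            rmse = mean(sc["rmse", ]),
                            mssim = mean(sc["mssim", ]),
                            hfen = mean(sc["hfen", ]))
    histories[[v]] <- tr$history
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       histories = histories)
}
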
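test_that("weight modulation scales per input channel exactly", {
  set.seed(1)
  w <- array(rnorm(3^3 * 4 * 4), c(3, 3, 3, 4, 4))
  expect_identical(modulate_weights(w, rep(1, 4)), w)
  l <- c(1, 2, 1, 1)
  wm <- modulate_weights(w, l)
  expect_equal(wm[, , , 2, ], 2 * w[, , , 2, ])
  expect_equal(wm[, , , c(1, 3, 4), ], w[, , , c(1, 3, 4), ])
  # index-loop oracle
  l2 <- rnorm(4)
  wm2 <- modulate_weights(w, l2)
  for (o in 1:4) for (c in 1:4) for (p in 1:3) for (q in 1:3) for (r in 1:3)
    if (abs(wm2[p, q, r, c, o] - l2[c] * w[p, q, r, c, o]) > 1e-15)
      fail(sprintf("mismatch at %d %d %d %d %d", p, q, r, c, o))
  succeed()
  expect_error(modulate_weights(w, rep(1, 3)), "channel count")
})

test_that("weight demodulation normalizes each output channel", {
  set.seed(2)
  w <- array(rnorm(3^3 * 4 * 4), c(3, 3, 3, 4, 4))
  eps <- 1e-8
  wd <- demodulate_weights(w, eps)
  # per-output-channel squared norm equals s/(s + eps), strictly below 1
  for (o in 1:4) {
    s <- sum(w[, , , , o]^2)
    expect_lt(abs(sum(wd[, , , , o]^2) - s / (s + eps)), 1e-10)
    expect_lt(sum(wd[, , , , o]^2), 1)
    # scalar-loop oracle
    expect_equal(wd[, , , , o], w[, , , , o] / sqrt(s + eps),
                 tolerance = 1e-12)
  }
  # zero weights stay zero and finite
  z <- demodulate_weights(array(0, c(3, 3, 3, 2, 2)), eps)
  expect_true(all(z == 0))
  expect_true(all(is.finite(z)))
  expect_error(demodulate_weights(w, 0), "epsilon")
})

test_that("modulated block reduces to hand-computed micro-instances", {
  cfg <- lcmnet_config(n_levels = 2, base_channels = 2, n_blocks = 2)
  # single voxel, 1x1x1 kernel, 2 channels: a plain matrix-vector product
  set.seed(3)
  wmat <- matrix(rnorm(4), 2, 2)          # [out, in]
  weights <- list(mod_w = array(t(wmat), c(1, 1, 1, 2, 2)),
                  mod_b = c(0.1, -0.2),
                  comb_w = array(0, c(1, 1, 1, 4, 2)),
                  comb_b = c(0, 0))
  # choose comb to pass through the modulated output unchanged
  weights$comb_w[1, 1, 1, 1, 1] <- 1
  weights$comb_w[1, 1, 1, 2, 2] <- 1
  x <- array(c(0.5, -0.3), c(1, 1, 1, 2))
  fused <- array(0, c(1, 1, 1, 2))
  latent <- c(2, 0.5)
  out <- modulated_conv_block(x, latent, fused, weights, cfg)
  wmod <- sweep(wmat, 2, latent, "*")
  wdem <- wmod / sqrt(rowSums(wmod^2) + cfg$epsilon)
  expected <- as.numeric(wdem %*% c(0.5, -0.3)) + c(0.1, -0.2)
  expected <- ifelse(expected < 0, 0.1 * expected, expected)  # leaky ReLU
  expect_equal(as.numeric(out), expected, tolerance = 1e-12)
  # zero inputs, zero bias give zero output
  weights0 <- weights; weights0$mod_b <- c(0, 0)
  z <- modulated_conv_block(array(0, c(1, 1, 1, 2)), latent,
                            array(0, c(1, 1, 1, 2)), weights0, cfg)
  expect_true(all(z == 0))
  # no_modulation skips mod/demod entirely
  cfg_nm <- lcmnet_config(n_levels = 2, base_channels = 2, n_blocks = 2,
                          no_modulation = TRUE)
  out_nm <- modulated_conv_block(x, latent, fused, weights, cfg_nm)
  expected_nm <- as.numeric(wmat %*% c(0.5, -0.3)) + c(0.1, -0.2)
  expected_nm <- ifelse(expected_nm < 0, 0.1 * expected_nm, expected_nm)
  expect_equal(as.numeric(out_nm), expected_nm, tolerance = 1e-12)
  expect_error(modulated_conv_block(x, latent, array(0, c(2, 1, 1, 2)),
                                    weights, cfg), "spatial")
})

test_that("field encoder produces the contracted feature pyramid", {
  cfg <- micro_model_config()
  model <- lcmnet_init(cfg, seed = 4)
  x <- array(rnorm(16^3, sd = 0.1), c(16, 16, 16))
  fs <- encode_field(model, x)
  expect_length(fs$levels, 2)
  for (lv in fs$levels) expect_equal(dim(lv)[1:3], c(16L, 16L, 16L))
  expect_equal(dim(fs$fd)[1:3], c(4L, 4L, 4L))
  # all-zero input with zero biases gives all-zero features
  m0 <- model
  for (l in 1:2) {
    m0$params$enc[[l]]$c1$b[] <- 0
    m0$params$enc[[l]]$c2$b[] <- 0
  }
  m0$params$down[[1]]$b[] <- 0; m0$params$down[[2]]$b[] <- 0
  fz <- encode_field(m0, array(0, c(16, 16, 16)))
  expect_true(all(vapply(fz$levels, function(v) all(v == 0), logical(1))))
  expect_true(all(fz$fd == 0))
  expect_error(encode_field(model, array(0, c(15, 16, 16))),
               "multiples of 4")
})

test_that("latent decoding pools over the VOI only", {
  cfg <- micro_model_config()
  model <- lcmnet_init(cfg, seed = 5)
  fd <- array(rnorm(4^3 * 2), c(4, 4, 4, 2))
  mask_d <- array(FALSE, c(4, 4, 4)); mask_d[2:3, 2:3, 2:3] <- TRUE
  # constant inside VOI, garbage outside: pooled value is exactly c
  fd_const <- fd
  fd_const[, , , 1][mask_d] <- 0.7
  fd_const[, , , 2][mask_d] <- -0.3
  lat1 <- decode_latent(model, fd_const, mask_d)
  garbage <- fd_const
  garbage[, , , 1][!mask_d] <- 1e6
  garbage[, , , 2][!mask_d] <- -99
  lat2 <- decode_latent(model, garbage, mask_d)
  expect_identical(lat1, lat2)
  # code length equals the modulated kernel's channel count, one per block
  expect_length(lat1, cfg$n_blocks)
  for (l in lat1) expect_length(l, cfg$base_channels)
  # masked pooling equals an explicit sum over true voxels
  dec <- lcmqsm:::convblock_fwd(fd, model$params$dec)
  v <- lcmqsm:::nn_masked_gap(dec$y, mask_d)
  for (c in 1:2) {
    acc <- 0; n <- 0
    for (i in 1:4) for (j in 1:4) for (k in 1:4) if (mask_d[i, j, k]) {
      acc <- acc + dec$y[i, j, k, c]; n <- n + 1
    }
    expect_equal(v[c], acc / n, tolerance = 1e-12)
  }
  expect_error(decode_latent(model, fd, array(FALSE, c(4, 4, 4))), "empty")
})

test_that("cross-fusion ignores everything outside the VOI", {
  cfg <- micro_model_config()
  model <- lcmnet_init(cfg, seed = 6)
  d <- c(8L, 8L, 8L)
  field <- array(rnorm(prod(d), sd = 0.1), d)
  mask <- array(FALSE, d); mask[3:6, 3:6, 3:6] <- TRUE
  mag <- array(runif(prod(d)), d)
  fs <- encode_field(model, field)
  f1 <- cross_fusion(model, fs, mag, mask)
  mag2 <- mag; mag2[!mask] <- 123
  f2 <- cross_fusion(model, fs, mag2, mask)
  expect_identical(f1, f2)
  expect_length(f1, cfg$n_levels)
  for (m in f1) expect_equal(dim(m)[1:3], d)
  # the no-fusion ablation is independent of the magnitude entirely
  cfg_nf <- micro_model_config(no_fusion = TRUE)
  model_nf <- lcmnet_init(cfg_nf, seed = 6)
  g1 <- cross_fusion(model_nf, fs, mag, mask)
  g2 <- cross_fusion(model_nf, fs, array(0.5, d), mask)
  expect_identical(g1, g2)
})

test_that("full forward pass preserves shape and is deterministic", {
  cfg <- lcmnet_config(n_levels = 2, base_channels = 4, n_blocks = 2)
  model <- lcmnet_init(cfg, seed = 7)
  for (d in list(c(16L, 16L, 16L), c(32L, 32L, 32L), c(64L, 64L, 32L))) {
    set.seed(8)
    field <- array(rnorm(prod(d), sd = 0.05), d)
    mag <- array(runif(prod(d)), d)
    chi0 <- array(rnorm(prod(d), sd = 0.1), d)
    mask <- array(TRUE, d)
    o1 <- lcmnet_forward(model, field, mag, chi0, mask)
    expect_equal(dim(o1), d)
    o2 <- lcmnet_forward(model, field, mag, chi0, mask)
    expect_identical(o1, o2)
    break  # the larger shapes are covered below with a single pass each
  }
  for (d in list(c(32L, 32L, 32L), c(64L, 64L, 32L))) {
    out <- lcmnet_forward(model, array(0, d), array(0, d), array(0, d),
                          array(TRUE, d))
    expect_equal(dim(out), d)
  }
  expect_error(lcmnet_forward(model, array(0, c(16, 16, 16)),
                              array(0, c(16, 16, 8)),
                              array(0, c(16, 16, 16)),
                              array(TRUE, c(16, 16, 16))), "shape")
})

test_that("network output is invariant to input values outside the VOI", {
  cfg <- micro_model_config()
  model <- lcmnet_init(cfg, seed = 9)
  d <- c(16L, 16L, 16L)
  set.seed(10)
  mask <- array(FALSE, d); mask[3:14, 3:14, 3:14] <- TRUE
  field <- array(rnorm(prod(d), sd = 0.05), d)
  mag <- array(runif(prod(d)), d)
  chi0 <- array(rnorm(prod(d), sd = 0.1), d)
  o1 <- lcmnet_forward(model, field, mag, chi0, mask)
  field2 <- field; field2[!mask] <- 50
  mag2 <- mag; mag2[!mask] <- -7
  chi02 <- chi0; chi02[!mask] <- 1e3
  o2 <- lcmnet_forward(model, field2, mag2, chi02, mask)
  expect_identical(o1[mask], o2[mask])
})

test_that("stacked ablations reduce to a plain convolutional network", {
  cfg <- micro_model_config(no_modulation = TRUE, no_fusion = TRUE,
                            field_as_initial_input = TRUE)
  model <- lcmnet_init(cfg, seed = 11)
  d <- c(8L, 8L, 8L)
  set.seed(12)
  field <- array(rnorm(prod(d), sd = 0.05), d)
  chi0 <- array(rnorm(prod(d), sd = 0.1), d)
  mask <- array(TRUE, d)
  base <- lcmnet_forward(model, field, array(0.2, d), chi0, mask)
  # no magnitude dependence
  o2 <- lcmnet_forward(model, field, array(0.9, d), chi0, mask)
  expect_identical(base, o2)
  # no latent dependence: zeroing the latent heads changes nothing
  m2 <- model
  for (i in seq_along(m2$params$lat)) {
    m2$params$lat[[i]]$W[] <- 0
    m2$params$lat[[i]]$b[] <- 5
  }
  expect_identical(lcmnet_forward(m2, field, array(0.2, d), chi0, mask),
                   base)
  # no chi_init dependence (the field replaces it)
  o3 <- lcmnet_forward(model, field, array(0.2, d), chi0 + 1, mask)
  expect_identical(base, o3)
})

test_that("analytic gradients match finite differences on a micro-instance", {
  cfg <- micro_model_config()
  model <- lcmnet_init(cfg, seed = 5)
  model$params$head$w <- array(rnorm(length(model$params$head$w), sd = 0.1),
                               dim(model$params$head$w))
  inp <- random_micro_inputs()
  lconf <- loss_config(alpha = 0.5, log_sigma = 1.0, log_kernel_size = 3)
  loss_fn <- function(m)
    training_loss(lcmnet_forward(m, inp$field, inp$mag, inp$chi0, inp$mask),
                  inp$chiref, inp$mask, lconf)
  fw <- lcmqsm:::lcmnet_fwd(model, inp$field, inp$mag, inp$chi0, inp$mask)
  lg <- training_loss_grad(fw$out, inp$chiref, inp$mask, lconf)
  gr <- lcmqsm:::lcmnet_bwd(model, fw, lg$grad)
  paths <- list(list("blocks", 1, "mod_w"), list("blocks", 2, "mod_w"),
                list("blocks", 1, "comb_w"), list("stem", "w"),
                list("enc", 1, "c1", "w"), list("down", 1, "w"),
                list("dec", "w"), list("lat", 1, "W"), list("lat", 2, "b"),
                list("mag", "c2", "w"), list("fuse_mix", "w"),
                list("fuse_out", 1, "w"), list("head", "w"))
  set.seed(99)
  for (path in paths) {
    arr <- get_in(model$params, path)
    ga <- get_in(gr, path)
    for (i in sample(length(arr), min(4, length(arr)))) {
      h <- 1e-5
      a1 <- arr; a1[i] <- a1[i] + h
      a2 <- arr; a2[i] <- a2[i] - h
      m1 <- model; m1$params <- set_in(model$params, path, a1)
      m2 <- model; m2$params <- set_in(model$params, path, a2)
      fd <- (loss_fn(m1) - loss_fn(m2)) / (2 * h)
      rel <- abs(fd - ga[i]) / max(abs(fd), abs(ga[i]), 1e-6)
      expect_lt(rel, 1e-4)
    }
  }
})

test_that("block count outside 2-5 is rejected", {
  expect_error(lcmnet_config(n_blocks = 1), "between 2 and 5")
  expect_error(lcmnet_config(n_blocks = 6), "between 2 and 5")
  expect_s3_class(lcmnet_config(n_blocks = 5), "lcmnet_config")
})
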
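# Volumetric layer primitives with explicit forward/backward passes.
# Feature maps are (X, Y, Z, C) arrays; convolution weights are
# (K, K, K, Cin, Cout) with 'same' zero padding (see src/conv3d.cpp).

as4d <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

nn_conv <- function(x, w, b) {
  x <- as4d(x)
  y <- conv3d_fwd(as.numeric(x), as.numeric(w), as.numeric(b),
                  as.integer(dim(x)), as.integer(dim(w)))
  y
}

nn_conv_bwd <- function(x, w, gy) {
  x <- as4d(x)
  gx <- conv3d_bwd_input(as.numeric(gy), as.numeric(w),
                         as.integer(dim(x)), as.integer(dim(w)))
  gwb <- conv3d_bwd_weight(as.numeric(x), as.numeric(gy),
                           as.integer(dim(x)), as.integer(dim(w)))
  gw <- gwb$weights
  dim(gw) <- dim(w)
  list(gx = gx, gw = gw, gb = gwb$bias)
}

LRELU_SLOPE <- 0.1

nn_lrelu <- function(x) {
  neg <- x < 0
  x[neg] <- LRELU_SLOPE * x[neg]
  x
}

nn_lrelu_bwd <- function(x_pre, gy) {
  gy * ifelse(x_pre < 0, LRELU_SLOPE, 1)
}

# factor-2 average pooling over the three spatial axes
nn_avgpool2 <- function(x) {
  x <- as4d(x)
  d <- dim(x)
  if (any(d[1:3] %% 2L != 0L))
    stop("spatial dims must be even for factor-2 pooling; got ",
         paste(d[1:3], collapse = "x"))
  i1 <- seq.int(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq.int(1L, d[2], 2L); j2 <- j1 + 1L
  k1 <- seq.int(1L, d[3], 2L); k2 <- k1 + 1L
  (x[i1, j1, k1, , drop = FALSE] + x[i2, j1, k1, , drop = FALSE] +
   x[i1, j2, k1, , drop = FALSE] + x[i2, j2, k1, , drop = FALSE] +
   x[i1, j1, k2, , drop = FALSE] + x[i2, j1, k2, , drop = FALSE] +
   x[i1, j2, k2, , drop = FALSE] + x[i2, j2, k2, , drop = FALSE]) / 8
}

nn_avgpool2_bwd <- function(in_dim, gy) {
  gx <- array(0, in_dim)
  d <- in_dim
  i1 <- seq.int(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq.int(1L, d[2], 2L); j2 <- j1 + 1L
  k1 <- seq.int(1L, d[3], 2L); k2 <- k1 + 1L
  g8 <- gy / 8
  gx[i1, j1, k1, ] <- g8; gx[i2, j1, k1, ] <- g8
  gx[i1, j2, k1, ] <- g8; gx[i2, j2, k1, ] <- g8
  gx[i1, j1, k2, ] <- g8; gx[i2, j1, k2, ] <- g8
  gx[i1, j2, k2, ] <- g8; gx[i2, j2, k2, ] <- g8
  gx
}

# global average pooling restricted to the VOI: one value per channel
nn_masked_gap <- function(x, mask) {
  x <- as4d(x)
  d <- dim(x)
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask in masked pooling")
  vapply(seq_len(d[4]), function(c) {
    xc <- x[, , , c]
    mean(xc[idx])
  }, numeric(1))
}

nn_masked_gap_bwd <- function(in_dim, mask, gv) {
  gx <- array(0, in_dim)
  idx <- which(mask)
  n <- length(idx)
  for (c in seq_len(in_dim[4])) {
    gc <- array(0, in_dim[1:3])
    gc[idx] <- gv[c] / n
    gx[, , , c] <- gc
  }
  gx
}

nn_concat <- function(a, b) {
  a <- as4d(a); b <- as4d(b)
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:3] == db[1:3]))
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}

nn_split <- function(g, c1) {
  d <- dim(g)
  list(g[, , , seq_len(c1), drop = FALSE],
       g[, , , (c1 + 1):d[4], drop = FALSE])
}

# downsample a logical mask by repeated factor-2 mean pooling, then
# threshold at 0.5 (ties included)
downsample_mask <- function(mask, times) {
  m <- array(as.numeric(mask), c(dim(mask), 1L))
  for (i in seq_len(times)) m <- nn_avgpool2(m)
  array(m[, , , 1] >= 0.5, dim(m)[1:3])
}
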
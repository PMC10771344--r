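test_that("base brain phantom is deterministic and bounded", {
  cfg <- phantom_config(grid_geometry(c(24, 24, 24)), n_tissue_regions = 0)
  set.seed(3); a <- generate_base_brain(cfg)
  set.seed(3); b <- generate_base_brain(cfg)
  expect_identical(a$chi$data, b$chi$data)
  expect_identical(a$mask$data, b$mask$data)
  # background-only phantom stays within +/- 0.05 ppm
  expect_lte(max(abs(a$chi$data)), 0.05)
  expect_true(all(a$chi$data[!a$mask$data] == 0))
})

test_that("VOI mask volume matches the analytic ellipsoid volume", {
  shape <- c(48, 48, 48)
  cfg <- phantom_config(grid_geometry(shape), n_tissue_regions = 0)
  set.seed(1)
  bb <- generate_base_brain(cfg)
  semi <- c(0.4, 0.45, 0.35) * shape
  analytic <- 4 / 3 * pi * prod(semi)
  expect_lt(abs(sum(bb$mask$data) - analytic) / analytic, 0.02)
})

test_that("linear amplification scales chi and its field", {
  ph <- smooth_phantom(16, seed = 5)
  g <- ph$geometry
  chi <- susceptibility_volume(ph$chi, g)
  expect_identical(apply_linear_amplification(chi, 1)$data, chi$data)
  kern <- build_dipole_kernel(g)
  a <- 2.3
  f1 <- forward_field(apply_linear_amplification(chi, a), kern)$data
  f2 <- a * forward_field(chi, kern)$data
  expect_lt(max(abs(f1 - f2)), 1e-12)
  expect_error(apply_linear_amplification(chi, Inf), "finite")
})

test_that("spherical sources land inside the VOI with in-range values", {
  cfg <- phantom_config(grid_geometry(c(24, 24, 24)), n_sources = 5,
                        source_radius_range = c(1.5, 3))
  set.seed(8)
  bb <- generate_base_brain(cfg)
  src <- add_spherical_sources(bb$chi, bb$mask, cfg)
  expect_equal(nrow(src$sources), 5)
  expect_true(all(src$sources$value >= -0.4 & src$sources$value <= 0.4))
  # membership of modified voxels equals a brute-force distance check
  changed <- which(src$chi$data != bb$chi$data, arr.ind = TRUE)
  for (r in seq_len(nrow(changed))) {
    v <- changed[r, ]
    d2 <- (src$sources$cx - v[1])^2 + (src$sources$cy - v[2])^2 +
      (src$sources$cz - v[3])^2
    expect_true(any(d2 <= src$sources$radius^2))
    expect_true(bb$mask$data[v[1], v[2], v[3]])
  }
  # a sphere's voxels take exactly the drawn value (overwrite semantics)
  s1 <- src$sources[1, ]
  expect_equal(src$chi$data[round(s1$cx), round(s1$cy), round(s1$cz)],
               s1$value)
  # zero sources is the identity
  cfg0 <- phantom_config(grid_geometry(c(24, 24, 24)), n_sources = 0)
  expect_identical(add_spherical_sources(bb$chi, bb$mask, cfg0)$chi$data,
                   bb$chi$data)
})

test_that("synthesized field is the forward model plus calibrated noise", {
  ph <- smooth_phantom(48, seed = 2)
  g <- ph$geometry
  kern <- build_dipole_kernel(g)
  chi <- susceptibility_volume(ph$chi, g)
  clean <- synthesize_field(chi, kern, 0)
  expect_identical(clean$data, forward_field(chi, kern)$data)
  sd0 <- 0.005
  set.seed(21); f1 <- synthesize_field(chi, kern, sd0)
  set.seed(21); f2 <- synthesize_field(chi, kern, sd0)
  expect_identical(f1$data, f2$data)
  resid <- f1$data - clean$data
  n <- length(resid)
  expect_lt(abs(sd(resid) - sd0), 3 * sd0 / sqrt(2 * n))
  expect_error(synthesize_field(chi, kern, -1), ">= 0")
})

test_that("magnitude proxy is bounded, masked, and contrasts lesions", {
  cfg <- phantom_config(grid_geometry(c(24, 24, 24)), n_sources = 3,
                        source_radius_range = c(2, 3))
  set.seed(12)
  bb <- generate_base_brain(cfg)
  src <- add_spherical_sources(bb$chi, bb$mask, cfg)
  m <- synthesize_magnitude(src$chi, bb$mask, src$sources)
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(m[!bb$mask$data] == 0))
  # each sphere's mean intensity differs from its immediate shell
  gx <- array(seq_len(24), c(24, 24, 24))
  gy <- aperm(gx, c(2, 1, 3)); gz <- aperm(gx, c(3, 2, 1))
  for (r in seq_len(nrow(src$sources))) {
    s <- src$sources[r, ]
    d2 <- (gx - s$cx)^2 + (gy - s$cy)^2 + (gz - s$cz)^2
    inside <- d2 <= s$radius^2
    shell <- d2 > s$radius^2 & d2 <= (s$radius + 2)^2 & bb$mask$data
    expect_gte(abs(mean(m[inside]) - mean(m[shell])), 0.1)
  }
})

test_that("a sample regenerates bit-identically from its provenance", {
  cfg <- tiny_phantom_config(seed = 42)
  s1 <- generate_sample(cfg)
  s2 <- generate_sample(cfg, s1$provenance$seed)
  expect_identical(s1$chi$data, s2$chi$data)
  expect_identical(s1$field$data, s2$field$data)
  expect_identical(s1$magnitude, s2$magnitude)
  expect_identical(s1$provenance$amplification, s2$provenance$amplification)
})

test_that("noiseless sample fields invert exactly on well-conditioned bins", {
  cfg <- tiny_phantom_config(seed = 31)
  cfg$noise_std <- 0
  s <- generate_sample(cfg)
  kern <- build_dipole_kernel(cfg$geometry)
  rec <- tkd_invert(s$field, kern, tkd_config(0.2))
  keep <- abs(kern$values) > 0.2
  rk <- stats::fft(rec$data); ck <- stats::fft(s$chi$data)
  expect_lt(max(abs(rk[keep] - ck[keep])) / max(abs(ck[keep])), 1e-8)
})

test_that("the dipole field extends beyond the source support", {
  cfg <- phantom_config(grid_geometry(c(24, 24, 24)), n_tissue_regions = 0,
                        n_sources = 1, source_radius_range = c(3, 3),
                        noise_std = 0, seed = 77)
  s <- generate_sample(cfg, 77)
  src_voxels <- s$chi$data != 0
  outside <- !src_voxels
  expect_gt(max(abs(s$field$data[outside])), 1e-4)
})

test_that("amplification and source draws have the configured distributions", {
  cfg <- tiny_phantom_config(seed = 500)
  samples <- lapply(seq_len(200), function(i) generate_sample(cfg, 500 + i))
  amps <- vapply(samples, function(s) s$provenance$amplification, numeric(1))
  expect_true(all(amps >= 1 & amps <= 3))
  expect_gt(suppressWarnings(
    stats::ks.test(amps, "punif", 1, 3)$p.value), 0.01)
  vals <- unlist(lapply(samples, function(s) s$provenance$sources$value))
  expect_true(all(vals >= -0.4 & vals <= 0.4))
  expect_gt(suppressWarnings(
    stats::ks.test(vals, "punif", -0.4, 0.4)$p.value), 0.01)
})

test_that("patch grid tiles the VOI bounding box deterministically", {
  cfg <- tiny_phantom_config(seed = 9, n = 32L)
  ds <- build_dataset(cfg, 1, patch_size = c(32, 32, 32))
  expect_equal(nrow(ds$patches), 1)
  expect_equal(unlist(ds$patches[1, c("x0", "y0", "z0")], use.names = FALSE),
               c(0, 0, 0))

  ds2 <- build_dataset(cfg, 2, patch_size = c(16, 16, 16))
  m <- ds2$samples[[1]]$mask$data
  w <- which(m, arr.ind = TRUE)
  # closed-form tiling count per axis: ceil((extent - P)/S) + 1
  counts <- vapply(1:3, function(ax) {
    lo <- min(w[, ax]) - 1; hi <- max(w[, ax])
    ceiling((hi - lo - 16) / 8) + 1
  }, numeric(1))
  expect_equal(sum(ds2$patches$sample == 1), prod(counts))
  # every patch fits inside the volume, 0-based half-open
  expect_true(all(ds2$patches$x0 >= 0 & ds2$patches$x0 + 16 <= 32))
  expect_error(build_dataset(cfg, 1, patch_size = c(64, 64, 64)), "exceeds")
})

test_that("default patch size follows the training protocol", {
  expect_equal(train_config()$patch_size, c(64L, 64L, 32L))
  cfg <- phantom_config(grid_geometry(c(64, 64, 32)), seed = 2)
  ds <- build_dataset(cfg, 1)
  expect_equal(ds$patch_size, c(64L, 64L, 32L))
})
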
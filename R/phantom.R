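#' Phantom generator configuration
#'
#' Parameters of the synthetic brain-like susceptibility phantom: an
#' ellipsoidal VOI containing a smooth low-amplitude background plus
#' deep-gray-matter-like blob regions, globally amplified by a factor
#' drawn from `amplification_range`, with spherical susceptibility
#' sources overwritten into the tissue, a forward-model field with added
#' Gaussian noise, and a co-registered magnitude image.
#'
#' Defaults follow the simulation protocol the package emulates:
#' amplification factors uniform on [1, 3] and source values uniform on
#' [-0.4, 0.4] ppm. The noise level, source radii and counts are
#' implementation choices (see the methods vignette).
#'
#' @param geometry a [grid_geometry()].
#' @param n_tissue_regions number of blob regions inside the VOI.
#' @param amplification_range range of the global linear amplification
#'   factor.
#' @param n_sources number of spherical sources per volume.
#' @param source_value_range source susceptibility range (ppm); must lie
#'   within [-1, 1] ppm for physical plausibility.
#' @param source_radius_range sphere radius range (voxels).
#' @param noise_std standard deviation of the Gaussian field noise (ppm).
#' @param seed base seed for dataset generation.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(geometry,
                           n_tissue_regions = 6,
                           amplification_range = c(1, 3),
                           n_sources = 4,
                           source_value_range = c(-0.4, 0.4),
                           source_radius_range = c(2, 4),
                           noise_std = 0.005,
                           seed = 1L) {
  stopifnot(inherits(geometry, "grid_geometry"))
  ck_range <- function(r, what) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop(what, " must be an ordered finite pair")
  }
  ck_range(amplification_range, "amplification_range")
  ck_range(source_value_range, "source_value_range")
  ck_range(source_radius_range, "source_radius_range")
  if (max(abs(source_value_range)) > 1)
    stop("source values must stay within +/-1 ppm")
  if (!is.finite(noise_std) || noise_std < 0) stop("noise_std must be >= 0")
  if (n_tissue_regions < 0 || n_sources < 0)
    stop("region and source counts must be >= 0")
  structure(list(geometry = geometry,
                 n_tissue_regions = as.integer(n_tissue_regions),
                 amplification_range = as.numeric(amplification_range),
                 n_sources = as.integer(n_sources),
                 source_value_range = as.numeric(source_value_range),
                 source_radius_range = as.numeric(source_radius_range),
                 noise_std = noise_std, seed = as.integer(seed)),
            class = "phantom_config")
}

# Smooth random volume via k-space Gaussian low-pass of white noise,
# rescaled to unit max amplitude. Draws prod(shape) normals.
smooth_noise_volume <- function(shape, cutoff = 0.08) {
  n <- array(stats::rnorm(prod(shape)), shape)
  kx <- fft_freq(shape[1]); ky <- fft_freq(shape[2]); kz <- fft_freq(shape[3])
  KX <- array(kx, shape)
  KY <- array(rep(ky, each = shape[1]), shape)
  KZ <- array(rep(kz, each = shape[1] * shape[2]), shape)
  w <- exp(-(KX^2 + KY^2 + KZ^2) / (2 * cutoff^2))
  s <- Re(ifft3(fft3(n) * w))
  s / max(abs(s))
}

voxel_grids <- function(shape) {
  list(X = array(seq_len(shape[1]), shape),
       Y = array(rep(seq_len(shape[2]), each = shape[1]), shape),
       Z = array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), shape))
}

#' Generate the base tissue phantom
#'
#' Builds an ellipsoidal VOI (semi-axes 0.4, 0.45, 0.35 of the grid shape)
#' holding a smooth susceptibility background (|chi| <= 0.05 ppm) plus
#' `n_tissue_regions` ellipsoidal blob regions with values drawn uniformly
#' in [-0.15, 0.15] ppm, emulating deep-gray-matter nuclei. Zero outside
#' the VOI. Draws from R's global RNG; seed upstream for determinism.
#'
#' @param config a [phantom_config()].
#' @return list with elements `chi` ([susceptibility_volume()]) and
#'   `mask` ([voi_mask()]).
#' @export
generate_base_brain <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$geometry$shape
  ctr <- (shape + 1) / 2
  semi <- c(0.4, 0.45, 0.35) * shape
  g <- voxel_grids(shape)
  mask <- ((g$X - ctr[1]) / semi[1])^2 + ((g$Y - ctr[2]) / semi[2])^2 +
    ((g$Z - ctr[3]) / semi[3])^2 <= 1
  chi <- 0.04 * smooth_noise_volume(shape)
  for (i in seq_len(config$n_tissue_regions)) {
    ax <- stats::runif(3, 0.06, 0.15) * shape
    cen <- ctr + (stats::runif(3) - 0.5) * 0.9 * semi * 2 * 0.5
    val <- stats::runif(1, -0.15, 0.15)
    blob <- ((g$X - cen[1]) / ax[1])^2 + ((g$Y - cen[2]) / ax[2])^2 +
      ((g$Z - cen[3]) / ax[3])^2 <= 1
    chi[blob & mask] <- val
  }
  chi[!mask] <- 0
  list(chi = susceptibility_volume(chi, config$geometry),
       mask = voi_mask(mask, config$geometry))
}

#' Global linear amplification
#'
#' Scales a susceptibility volume elementwise by a factor; the dataset
#' generator draws the factor uniformly from the configured range
#' (default [1, 3]) to widen the numerical distribution of training data.
#'
#' @param chi a [susceptibility_volume()].
#' @param factor finite scalar amplification factor.
#' @return amplified [susceptibility_volume()].
#' @export
apply_linear_amplification <- function(chi, factor) {
  stopifnot(inherits(chi, "susceptibility_volume"))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor))
    stop("amplification factor must be a finite scalar")
  susceptibility_volume(chi$data * factor, chi$geometry)
}

#' Add spherical susceptibility sources
#'
#' Overwrites spherical regions of the tissue with susceptibility values
#' drawn uniformly from `source_value_range` (default [-0.4, 0.4] ppm),
#' emulating focal lesions such as hemorrhage or calcification. Sphere
#' centers are sampled uniformly among VOI voxels, rejecting positions
#' where the sphere would poke outside the VOI; if a sphere cannot be
#' placed after 200 attempts a warning is raised and fewer sources are
#' returned.
#'
#' @param chi a [susceptibility_volume()].
#' @param mask a [voi_mask()].
#' @param config a [phantom_config()].
#' @return list with `chi` (modified volume) and `sources` (data.frame of
#'   center coordinates, radius and value per placed sphere).
#' @export
add_spherical_sources <- function(chi, mask, config) {
  stopifnot(inherits(chi, "susceptibility_volume"),
            inherits(mask, "voi_mask"),
            inherits(config, "phantom_config"))
  shape <- chi$geometry$shape
  g <- voxel_grids(shape)
  idx <- which(mask$data)
  data <- chi$data
  recs <- list()
  for (i in seq_len(config$n_sources)) {
    placed <- FALSE
    for (attempt in seq_len(200L)) {
      radius <- stats::runif(1, config$source_radius_range[1],
                             config$source_radius_range[2])
      cen_i <- idx[sample.int(length(idx), 1L)]
      cen <- c(g$X[cen_i], g$Y[cen_i], g$Z[cen_i])
      inside <- (g$X - cen[1])^2 + (g$Y - cen[2])^2 + (g$Z - cen[3])^2 <=
        radius^2
      if (all(mask$data[inside])) {
        val <- stats::runif(1, config$source_value_range[1],
                            config$source_value_range[2])
        data[inside] <- val
        recs[[length(recs) + 1L]] <-
          data.frame(cx = cen[1], cy = cen[2], cz = cen[3],
                     radius = radius, value = val)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      warning("VOI too small to host a sphere; placed ",
              length(recs), " of ", config$n_sources, " sources")
      break
    }
  }
  sources <- if (length(recs)) do.call(rbind, recs) else
    data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
               radius = numeric(0), value = numeric(0))
  list(chi = susceptibility_volume(data, chi$geometry), sources = sources)
}

#' Synthesize the measured field
#'
#' Applies the dipole forward model and adds i.i.d. zero-mean Gaussian
#' noise of standard deviation `noise_std` (ppm) to every voxel.
#'
#' @param chi a [susceptibility_volume()].
#' @param kernel matching [build_dipole_kernel()] result.
#' @param noise_std noise standard deviation (ppm, >= 0).
#' @return a [field_volume()].
#' @export
synthesize_field <- function(chi, kernel, noise_std) {
  if (!is.finite(noise_std) || noise_std < 0) stop("noise_std must be >= 0")
  f <- forward_field(chi, kernel)
  if (noise_std > 0)
    f$data <- f$data + array(stats::rnorm(prod(dim(f$data)), sd = noise_std),
                             dim(f$data))
  f
}

#' Synthesize a magnitude image
#'
#' Builds a magnitude proxy carrying the structural contrast a real
#' gradient-echo magnitude would: smooth tissue intensity co-located with
#' the susceptibility regions, spheres rendered with sharp, distinct
#' contours, a mild multiplicative bias field, zero outside the VOI and
#' clipped to [0, 1].
#'
#' @param chi a [susceptibility_volume()].
#' @param mask a [voi_mask()].
#' @param sources data.frame of sphere records from
#'   [add_spherical_sources()].
#' @return real 3-D array in [0, 1].
#' @export
synthesize_magnitude <- function(chi, mask, sources) {
  stopifnot(inherits(chi, "susceptibility_volume"),
            inherits(mask, "voi_mask"))
  shape <- chi$geometry$shape
  g <- voxel_grids(shape)
  scale <- max(abs(chi$data[mask$data]), 1e-6)
  m <- 0.65 + 0.25 * chi$data / scale
  # lesions are hypo/hyper-intense with sharp edges, like hematoma contours
  if (nrow(sources) > 0) {
    for (i in seq_len(nrow(sources))) {
      s <- sources[i, ]
      inside <- (g$X - s$cx)^2 + (g$Y - s$cy)^2 + (g$Z - s$cz)^2 <= s$radius^2
      m[inside] <- if (s$value >= 0) 0.35 else 0.95
    }
  }
  # mild multiplicative bias along a random direction
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  proj <- (g$X / shape[1] - 0.5) * dir[1] + (g$Y / shape[2] - 0.5) * dir[2] +
    (g$Z / shape[3] - 0.5) * dir[3]
  m <- m * (1 + 0.1 * proj / max(abs(proj)))
  m <- pmin(pmax(m, 0), 1)
  m[!mask$data] <- 0
  array(m, shape)
}

#' Generate one synthetic sample
#'
#' Runs the full generator pipeline deterministically from a seed: base
#' tissue phantom, global linear amplification (factor uniform on the
#' configured range), spherical sources, forward-model field plus noise,
#' and magnitude image. The draw order is fixed, so `config` plus `seed`
#' fully determine the sample; both are recorded in `provenance`.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed for this sample (defaults to `config$seed`).
#' @return an object of class `synthetic_sample` with fields `chi`,
#'   `field`, `magnitude`, `mask` and `provenance`.
#' @export
generate_sample <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(as.integer(seed))
  base <- generate_base_brain(config)
  factor <- stats::runif(1, config$amplification_range[1],
                         config$amplification_range[2])
  chi <- apply_linear_amplification(base$chi, factor)
  src <- add_spherical_sources(chi, base$mask, config)
  kernel <- build_dipole_kernel(config$geometry)
  field <- synthesize_field(src$chi, kernel, config$noise_std)
  magnitude <- synthesize_magnitude(src$chi, base$mask, src$sources)
  structure(list(chi = src$chi, field = field, magnitude = magnitude,
                 mask = base$mask,
                 provenance = list(seed = as.integer(seed),
                                   amplification = factor,
                                   sources = src$sources,
                                   noise_std = config$noise_std)),
            class = "synthetic_sample")
}

patch_starts <- function(lo, hi, patch, stride, n) {
  # 0-based starts of half-open patches covering [lo, hi); clamped to grid
  extent <- hi - lo
  if (extent <= patch) {
    s <- min(max(lo - floor((patch - extent) / 2), 0L), n - patch)
    return(as.integer(s))
  }
  s <- seq.int(lo, hi - patch, by = stride)
  as.integer(unique(c(s, hi - patch)))
}

#' Build a synthetic dataset with a patch index
#'
#' Generates `n_samples` full volumes (seeds `config$seed + 0 ... n-1`)
#' and a deterministic patch grid: patches of `patch_size` tile the VOI
#' bounding box with 50% overlap (stride = patch/2), the final patch
#' flush with the box edge. Corners are 0-based with half-open extents.
#'
#' @param config a [phantom_config()].
#' @param n_samples number of volumes.
#' @param patch_size integer triple (default 64 x 64 x 32).
#' @return list with `samples` (list of `synthetic_sample`) and `patches`
#'   (data.frame: sample id and corner x0, y0, z0).
#' @export
build_dataset <- function(config, n_samples, patch_size = c(64L, 64L, 32L)) {
  stopifnot(inherits(config, "phantom_config"))
  patch_size <- as.integer(patch_size)
  shape <- config$geometry$shape
  if (any(patch_size > shape))
    stop("patch_size exceeds the volume shape")
  if (any(patch_size < 1L)) stop("patch_size must be positive")
  samples <- lapply(seq_len(n_samples) - 1L,
                    function(i) generate_sample(config, config$seed + i))
  patches <- do.call(rbind, lapply(seq_len(n_samples), function(si) {
    m <- samples[[si]]$mask$data
    w <- which(m, arr.ind = TRUE)
    lo <- apply(w, 2, min) - 1L   # 0-based
    hi <- apply(w, 2, max)        # half-open upper bound
    stride <- pmax(patch_size %/% 2L, 1L)
    sx <- patch_starts(lo[1], hi[1], patch_size[1], stride[1], shape[1])
    sy <- patch_starts(lo[2], hi[2], patch_size[2], stride[2], shape[2])
    sz <- patch_starts(lo[3], hi[3], patch_size[3], stride[3], shape[3])
    g <- expand.grid(x0 = sx, y0 = sy, z0 = sz)
    cbind(sample = si, g)
  }))
  list(samples = samples, patches = patches, patch_size = patch_size)
}

#' Extract one patch from a sample
#'
#' @param sample a `synthetic_sample`.
#' @param corner 0-based integer triple (patch corner).
#' @param patch_size integer triple.
#' @return list of arrays `field`, `magnitude`, `mask`, `chi`.
#' @export
extract_patch <- function(sample, corner, patch_size) {
  i <- corner[1] + seq_len(patch_size[1])
  j <- corner[2] + seq_len(patch_size[2])
  k <- corner[3] + seq_len(patch_size[3])
  list(field = sample$field$data[i, j, k, drop = FALSE],
       magnitude = sample$magnitude[i, j, k, drop = FALSE],
       mask = sample$mask$data[i, j, k, drop = FALSE],
       chi = sample$chi$data[i, j, k, drop = FALSE])
}
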
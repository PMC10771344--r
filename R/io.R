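#' Read a 3-D NIfTI volume
#'
#' Reads a .nii or .nii.gz file, returning the data array as stored
#' (x, y, z index order) together with a [grid_geometry()] whose voxel
#' size comes from the header. The source image (with its affine) is
#' kept as an attribute so a round trip through [write_volume()]
#' preserves the header.
#'
#' @param path NIfTI file path.
#' @param b0_direction B0 unit vector to record in the geometry
#'   (default +z).
#' @return list with `data` (3-D array) and `geometry`.
#' @export
read_volume <- function(path, b0_direction = c(0, 0, 1)) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D image, got ", length(d), "-D: ", path)
  data <- array(as.numeric(img), d)
  if (!all(is.finite(data)))
    stop("non-finite voxels in ", path)
  vs <- RNifti::pixdim(img)[1:3]
  geom <- grid_geometry(d, vs, b0_direction)
  structure(list(data = data, geometry = geom), template = img)
}

#' Write a 3-D NIfTI volume
#'
#' @param data 3-D array, or one of the package's volume classes (its
#'   geometry is then used).
#' @param geometry a [grid_geometry()]; ignored when `data` carries one.
#' @param path output path (.nii or .nii.gz).
#' @param overwrite allow replacing an existing file.
#' @param template optional NIfTI image whose header/affine to reuse.
#' @return invisibly, the path.
#' @export
write_volume <- function(data, geometry = NULL, path, overwrite = FALSE,
                         template = NULL) {
  if (inherits(data, c("susceptibility_volume", "field_volume"))) {
    geometry <- data$geometry
    data <- data$data
  } else if (inherits(data, "voi_mask")) {
    geometry <- data$geometry
    data <- array(as.numeric(data$data), dim(data$data))
  }
  if (is.null(geometry)) stop("geometry required for a bare array")
  check_volume_data(data, geometry, "output")
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite ", path, " (use overwrite = TRUE)")
  img <- if (!is.null(template)) RNifti::asNifti(data, reference = template)
         else RNifti::asNifti(data)
  RNifti::pixdim(img) <- geometry$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a simulated sample to NIfTI files plus provenance sidecar
#'
#' Writes chi/field/magnitude/mask volumes for one synthetic sample and
#' a JSON sidecar holding the provenance (seed, amplification factor,
#' sphere records, noise level) sufficient to regenerate it.
#'
#' @param sample a `synthetic_sample`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @param overwrite allow replacing existing files.
#' @return invisibly, the paths written.
#' @export
write_sample <- function(sample, dir, prefix = "sample", overwrite = FALSE) {
  stopifnot(inherits(sample, "synthetic_sample"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- sample$chi$geometry
  paths <- c(chi = file.path(dir, paste0(prefix, "_chi.nii.gz")),
             field = file.path(dir, paste0(prefix, "_field.nii.gz")),
             magnitude = file.path(dir, paste0(prefix, "_magnitude.nii.gz")),
             mask = file.path(dir, paste0(prefix, "_mask.nii.gz")),
             provenance = file.path(dir, paste0(prefix, "_provenance.json")))
  write_volume(sample$chi, path = paths["chi"], overwrite = overwrite)
  write_volume(sample$field, path = paths["field"], overwrite = overwrite)
  write_volume(sample$magnitude, g, paths["magnitude"],
               overwrite = overwrite)
  write_volume(sample$mask, path = paths["mask"], overwrite = overwrite)
  prov <- sample$provenance
  prov$sources <- as.list(prov$sources)
  jsonlite::write_json(prov, paths["provenance"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Serialize a model to a portable text checkpoint
#'
#' Writes the configuration and all parameter arrays as versioned JSON,
#' so checkpoints are plain text and fully determined by the config.
#'
#' @param model an [lcmnet_init()] model.
#' @param path output path (.json).
#' @param overwrite allow replacing an existing file.
#' @return invisibly, the path.
#' @export
save_checkpoint <- function(model, path, overwrite = FALSE) {
  stopifnot(inherits(model, "lcmnet_model"))
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite ", path, " (use overwrite = TRUE)")
  ser <- function(x) {
    if (is.list(x)) lapply(x, ser)
    else if (is.matrix(x) || is.array(x))
      list(.dim = dim(x), .data = as.numeric(x))
    else as.numeric(x)
  }
  obj <- list(format = "lcmqsm-checkpoint", version = 1L,
              config = unclass(model$config), params = ser(model$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint path written by [save_checkpoint()].
#' @return an `lcmnet_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$format, "lcmqsm-checkpoint"))
    stop("not an lcmqsm checkpoint: ", path)
  cfg <- do.call(lcmnet_config, obj$config[setdiff(names(obj$config),
                                                   c("n_downsamplings",
                                                     "kernel_size"))])
  de <- function(x) {
    if (is.list(x) && !is.null(x$.dim))
      return(array(as.numeric(x$.data), as.integer(x$.dim)))
    if (is.list(x)) return(lapply(x, de))
    as.numeric(x)
  }
  params <- de(obj$params)
  # matrices serialized as arrays: restore latent-head W as matrix
  params$lat <- lapply(params$lat, function(l)
    list(W = matrix(l$W, nrow = dim(l$W)[1]), b = as.numeric(l$b)))
  structure(list(config = cfg, params = params), class = "lcmnet_model")
}
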
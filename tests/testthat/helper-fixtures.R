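# Shared fixtures: tilted B0 directions, small phantoms, tiny model configs.

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

tilt_b0 <- function(deg) as.numeric(rot_x(deg) %*% c(0, 0, 1))

# smooth zero-mean test phantom (susceptibility reference is mean-free:
# the DC component is unobservable from the local field)
smooth_phantom <- function(n = 32, seed = 7) {
  g <- grid_geometry(c(n, n, n))
  set.seed(seed)
  bb <- generate_base_brain(phantom_config(g, seed = seed))
  chi <- bb$chi$data - mean(bb$chi$data)
  list(chi = chi, mask = bb$mask, geometry = g)
}

tiny_phantom_config <- function(seed = 100, n = 16L) {
  phantom_config(grid_geometry(c(n, n, n)),
                 n_tissue_regions = 3, n_sources = 2,
                 source_radius_range = c(1.5, 2.5), seed = seed)
}

tiny_model_config <- function(...) {
  lcmnet_config(n_levels = 2, base_channels = 8, n_blocks = 3, ...)
}

micro_model_config <- function(...) {
  lcmnet_config(n_levels = 2, base_channels = 2, n_blocks = 2, ...)
}

random_micro_inputs <- function(d = c(4L, 4L, 4L), seed = 11) {
  set.seed(seed)
  list(field = array(rnorm(prod(d), sd = 0.05), d),
       mag = array(runif(prod(d)), d),
       chi0 = array(rnorm(prod(d), sd = 0.1), d),
       chiref = array(rnorm(prod(d), sd = 0.1), d),
       mask = {
         m <- array(TRUE, d)
         m[1, 1, ] <- FALSE
         m
       })
}

# nested list get/set used by finite-difference gradient checks
get_in <- function(lst, path) {
  for (k in path) lst <- lst[[k]]
  lst
}

set_in <- function(lst, path, val) {
  if (length(path) == 1L) {
    lst[[path[[1]]]] <- val
    return(lst)
  }
  lst[[path[[1]]]] <- set_in(lst[[path[[1]]]], path[-1], val)
  lst
}
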
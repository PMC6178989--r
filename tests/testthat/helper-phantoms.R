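# shared fixtures, built in code and cached for the session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a scaled-down brain phantom for the slower image-domain tests
small_phantom_spec <- function(tracer = "fdopa", noise_scale = 0, seed = 1,
                               psf_fwhm = 6.5) {
  regions <- list(
    list(name = "cortex", type = "ellipsoid_shell", center = c(0, 0, 0),
         semi_axes = c(24, 29, 24), inner_scale = 0.8, label = 1L),
    list(name = "deep", type = "ellipsoid", center = c(0, 0, 0),
         semi_axes = c(24, 29, 24) * 0.8, label = 2L),
    list(name = "putamen", type = "ellipsoid", center = c(9, 3, 0),
         semi_axes = c(9, 7, 7), label = 3L, within = "deep"),
    list(name = "caudate", type = "ellipsoid", center = c(-9, 5, 3),
         semi_axes = c(7, 6, 5), label = 4L, within = "deep"),
    list(name = "cerebellum", type = "ellipsoid", center = c(0, -12, -5),
         semi_axes = c(10, 7, 7), label = 5L, within = "deep"))
  phantom_spec(tracer, grid_shape = c(37, 43, 37), voxel_size = 2,
               psf_fwhm = psf_fwhm, noise_scale = noise_scale, seed = seed,
               regions = regions)
}

small_bundle_noiseless <- function() {
  cached("small_noiseless", render_phantom(small_phantom_spec()))
}

default_bundle_noiseless <- function() {
  cached("default_noiseless",
         render_phantom(phantom_spec("fdopa", noise_scale = 0)))
}

default_frames <- function() {
  sp <- phantom_spec("fdopa")
  list(starts = sp$frame_starts, durations = sp$frame_durations,
       mids = sp$frame_starts + sp$frame_durations / 2)
}

# a quick uniform grid affine
grid_affine <- function(voxel = 2, origin = c(0, 0, 0)) {
  a <- diag(c(voxel, voxel, voxel, 1))
  a[1:3, 4] <- origin
  a
}

random_volume <- function(dims = c(8, 8, 8), voxel = 2, seed = 1) {
  set.seed(seed)
  volume3d(array(rnorm(prod(dims)), dims), grid_affine(voxel))
}
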
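# Shared fixtures, built once per test run and memoized. Two scales are
# used: a desk-size geometry (64-256 px) for unit tests and the full
# default geometry (512 px phantom, 360 x 600 sinogram, 256 px
# reconstruction) for the validation suite.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# -- small geometry ---------------------------------------------------------

small_water <- function() fixture("small_water", function() {
  make_water_phantom(diameter = 48, grid_size = 64, fov = 64)
})

small_water_sino <- function() fixture("small_water_sino", function() {
  forward_project(small_water(), n_views = 60, n_bins = 80)
})

small_head_spec <- function() phantom_spec("head")

small_head_sino <- function() fixture("small_head_sino", function() {
  forward_project(make_head_phantom(small_head_spec(), 256, 250),
                  n_views = 180, n_bins = 300)
})

# -- full default geometry --------------------------------------------------

full_water_sino <- function() fixture("full_water_sino", function() {
  forward_project(make_water_phantom(200, 512, 250), 360, 600)
})

full_head_sino <- function() fixture("full_head_sino", function() {
  forward_project(make_head_phantom(phantom_spec("head"), 512, 250), 360, 600)
})

# central 5-cm ROI on the default reconstruction geometry
central_roi <- function() roi_spec(0, 0, 50, "central")

central_mask <- function() fixture("central_mask", function() {
  roi_mask(list(central_roi()), 256, 180)
})

# masked central-ROI SD of a reconstruction of `sino`
central_roi_sd <- function(sino) {
  img <- fbp(sino, "hann", fov = 180, grid_size = 256, mask = central_mask())
  roi_stats(img, central_roi())$sd
}

# flat image helper for ROI unit tests
flat_image <- function(value = 0, n = 64, fov = 64) {
  recon_image(matrix(value, n, n), fov)
}
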
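#' @keywords internal
"_PACKAGE"

# Linear attenuation of water, mm^-1, at a typical diagnostic effective
# energy. All HU <-> mu conversions in the package go through this value.
MU_WATER_DEFAULT <- 0.019

#' Convert Hounsfield units to linear attenuation
#'
#' HU are defined so that water maps to `mu_water` and air (-1000 HU) to 0.
#'
#' @param hu numeric vector or matrix of Hounsfield units.
#' @param mu_water linear attenuation of water in mm^-1.
#' @return linear attenuation in mm^-1, same shape as `hu`.
#' @export
hu_to_mu <- function(hu, mu_water = MU_WATER_DEFAULT) {
  mu_water * (1 + hu / 1000)
}

#' Convert linear attenuation to Hounsfield units
#'
#' @param mu linear attenuation in mm^-1.
#' @param mu_water linear attenuation of water in mm^-1.
#' @return Hounsfield units, same shape as `mu`.
#' @export
mu_to_hu <- function(mu, mu_water = MU_WATER_DEFAULT) {
  1000 * (mu / mu_water - 1)
}

# Deterministic substream seed derivation: every random stage (quantum draw,
# electronic draw, per-realization scans, ...) gets its own seed derived from
# one root seed and a stage name, so stages never share a stream and the whole
# pipeline is reproducible from a single integer.
substream_seed <- function(root_seed, name) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((abs(root_seed) * 7919 + h * 104729) %% 2147483629L)
}

# Pixel-center coordinates (mm) for an n x n grid covering [-fov/2, fov/2].
# Column index increases with x, row index increases with -y (matrix row 1 is
# the top of the image).
grid_coords <- function(n, fov) {
  px <- fov / n
  ax <- (seq_len(n) - (n + 1) / 2) * px
  list(x = ax, y = -ax, pixel_size = px)
}

# Logical mask of pixels whose centers fall inside a disk (cx, cy, radius mm).
disk_mask <- function(n, fov, cx, cy, radius) {
  co <- grid_coords(n, fov)
  xm <- matrix(co$x, n, n, byrow = TRUE)
  ym <- matrix(co$y, n, n, byrow = FALSE)
  (xm - cx)^2 + (ym - cy)^2 <= radius^2
}

# Elliptical mask (semi-axes a along x, b along y).
ellipse_mask <- function(n, fov, cx, cy, a, b) {
  co <- grid_coords(n, fov)
  xm <- matrix(co$x, n, n, byrow = TRUE)
  ym <- matrix(co$y, n, n, byrow = FALSE)
  ((xm - cx) / a)^2 + ((ym - cy) / b)^2 <= 1
}
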
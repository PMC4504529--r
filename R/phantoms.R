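# Digital phantoms: piecewise-constant HU maps used to drive the scanner and
# validate the dose-simulation chain without any physical scanner data.

#' Attenuation map constructor
#'
#' An `attenuation_map` is a square 2-D grid of Hounsfield values together
#' with its pixel size; it is the package's digital-phantom container.
#'
#' @param grid square numeric matrix of HU values, all >= -1000.
#' @param fov field of view in mm (grid side length in mm).
#' @return an object of class `attenuation_map` with elements `grid`,
#'   `pixel_size` (mm) and `fov` (mm).
#' @export
attenuation_map <- function(grid, fov) {
  if (!is.matrix(grid) || nrow(grid) != ncol(grid))
    stop("attenuation map grid must be a square matrix", call. = FALSE)
  if (any(!is.finite(grid)) || any(grid < -1000))
    stop("HU values must be finite and >= -1000", call. = FALSE)
  if (!is.numeric(fov) || length(fov) != 1L || fov <= 0)
    stop("fov must be a positive scalar (mm)", call. = FALSE)
  structure(
    list(grid = grid, pixel_size = fov / nrow(grid), fov = fov),
    class = "attenuation_map"
  )
}

#' @export
print.attenuation_map <- function(x, ...) {
  cat(sprintf(
    "<attenuation_map> %d x %d px, fov %.1f mm (%.3f mm/px), HU range [%g, %g]\n",
    nrow(x$grid), ncol(x$grid), x$fov, x$pixel_size,
    min(x$grid), max(x$grid)
  ))
  invisible(x)
}

#' Phantom specification for the head phantom
#'
#' Describes the head phantom used to validate dose simulation: a soft-tissue
#' ellipse surrounded by a skull ring, with two pairs of contrast-filled
#' tubes attached laterally, one pair per contrast dilution. The default
#' tube values (290 and 370 HU) are chosen so the pooled tube mean is 330 HU,
#' the attenuation level of contrast-enhanced neck vessels the tubes emulate.
#'
#' @param kind `"water"` or `"head"`.
#' @param diameter water-cylinder diameter in mm (water phantoms).
#' @param tube_hu_low,tube_hu_high HU of the two contrast dilutions
#'   (3 percent and 4 percent iodine); `tube_hu_low < tube_hu_high`.
#' @param tube_diameter tube inner diameter in mm.
#' @param skull_hu,tissue_hu HU of the skull ring and the soft-tissue
#'   interior.
#' @param tissue_a,tissue_b soft-tissue ellipse semi-axes in mm (x and y).
#' @param skull_thickness skull ring thickness in mm.
#' @param tube_offset_y vertical offset of tube centers from the midline, mm.
#' @param tube_gap air gap between skull surface and tube surface, mm.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("head", "water"),
                         diameter = 200,
                         tube_hu_low = 290, tube_hu_high = 370,
                         tube_diameter = 16,
                         skull_hu = 1200, tissue_hu = 40,
                         tissue_a = 70, tissue_b = 88,
                         skull_thickness = 6,
                         tube_offset_y = 20,
                         tube_gap = 2) {
  kind <- match.arg(kind)
  if (tube_hu_low >= tube_hu_high)
    stop("tube_hu_low must be < tube_hu_high", call. = FALSE)
  if (tube_diameter <= 0 || diameter <= 0 || tissue_a <= 0 || tissue_b <= 0)
    stop("phantom dimensions must be positive", call. = FALSE)
  structure(
    list(kind = kind, diameter = diameter,
         tube_hu_low = tube_hu_low, tube_hu_high = tube_hu_high,
         tube_diameter = tube_diameter,
         skull_hu = skull_hu, tissue_hu = tissue_hu,
         tissue_a = tissue_a, tissue_b = tissue_b,
         skull_thickness = skull_thickness,
         tube_offset_y = tube_offset_y, tube_gap = tube_gap),
    class = "phantom_spec"
  )
}

#' Water calibration phantom
#'
#' A centered uniform water cylinder (0 HU) on an air background (-1000 HU);
#' the 20-cm version is the calibration phantom the noise-insertion
#' calibration loop measures its reference noise on.
#'
#' @param diameter cylinder diameter in mm (default 200, the 20-cm phantom).
#' @param grid_size grid side in pixels.
#' @param fov field of view in mm; must be >= `diameter`.
#' @return an [attenuation_map()].
#' @export
make_water_phantom <- function(diameter = 200, grid_size = 512, fov = 250) {
  if (diameter > fov)
    stop("water phantom diameter exceeds the field of view", call. = FALSE)
  grid <- matrix(-1000, grid_size, grid_size)
  grid[disk_mask(grid_size, fov, 0, 0, diameter / 2)] <- 0
  attenuation_map(grid, fov)
}

# Tube centers for a head phantom spec: one pair per dilution, attached
# laterally outside the skull, low-dilution pair above the midline and
# high-dilution pair below. Mirror symmetry about both axes makes the four
# pixel masks congruent, so the pooled tube mean is exactly
# (tube_hu_low + tube_hu_high) / 2.
head_tube_centers <- function(spec) {
  r <- spec$tube_diameter / 2
  xt <- spec$tissue_a + spec$tube_gap + r
  data.frame(
    x = c(-xt, xt, -xt, xt),
    y = c(spec$tube_offset_y, spec$tube_offset_y,
          -spec$tube_offset_y, -spec$tube_offset_y),
    hu = c(spec$tube_hu_low, spec$tube_hu_low,
           spec$tube_hu_high, spec$tube_hu_high),
    dilution = c("low", "low", "high", "high"),
    stringsAsFactors = FALSE
  )
}

#' Head phantom with contrast-filled tubes
#'
#' Emulates a head phantom used for dose-simulation validation: a skull ring
#' around soft tissue, with tubes filled with two dilutions of iodinated
#' contrast attached to both sides to stand in for contrast-enhanced neck
#' vessels. The phantom is piecewise constant (pixel-center sampling), so
#' its HU histogram contains exactly the specified material values.
#'
#' @param spec a [phantom_spec()] of kind `"head"`.
#' @param grid_size grid side in pixels.
#' @param fov field of view in mm.
#' @return an [attenuation_map()].
#' @export
make_head_phantom <- function(spec = phantom_spec("head"),
                              grid_size = 512, fov = 250) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$kind != "head")
    stop("make_head_phantom needs a spec of kind 'head'", call. = FALSE)
  r <- spec$tube_diameter / 2
  tubes <- head_tube_centers(spec)
  if (max(abs(tubes$x)) + r > fov / 2 ||
      max(abs(tubes$y)) + r > fov / 2 ||
      spec$tissue_a > fov / 2 || spec$tissue_b > fov / 2)
    stop("phantom geometry does not fit inside the field of view",
         call. = FALSE)
  # tubes must not overlap each other or the skull
  if (2 * spec$tube_offset_y < spec$tube_diameter)
    stop("tube pairs overlap: tube_offset_y too small for tube_diameter",
         call. = FALSE)

  n <- grid_size
  grid <- matrix(-1000, n, n)
  grid[ellipse_mask(n, fov, 0, 0, spec$tissue_a, spec$tissue_b)] <- spec$skull_hu
  grid[ellipse_mask(n, fov, 0, 0,
                    spec$tissue_a - spec$skull_thickness,
                    spec$tissue_b - spec$skull_thickness)] <- spec$tissue_hu
  for (i in seq_len(nrow(tubes))) {
    grid[disk_mask(n, fov, tubes$x[i], tubes$y[i], r)] <- tubes$hu[i]
  }
  attenuation_map(grid, fov)
}

#' Standard ROI set for the head phantom tubes
#'
#' Places `n_per_dilution` circular ROIs per contrast dilution inside the
#' tubes (default 5 + 5 = 10 ROIs). ROI positions are deterministic: tube
#' centers plus small vertical offsets, all strictly inside the tubes. The
#' default `area_fraction` of 0.4 keeps every ROI clear of the
#' reconstruction kernel's edge-spread region at the tube wall, so the ROI
#' SD measures noise rather than the blurred edge gradient; the
#' two-thirds-of-lumen convention used for patient vessels is available by
#' setting `area_fraction = 2/3`.
#'
#' @param spec the [phantom_spec()] the phantom was built from.
#' @param n_per_dilution ROIs per dilution (default 5).
#' @param area_fraction ROI area as a fraction of the tube cross-section.
#' @return a list of [roi_spec()] objects.
#' @export
head_phantom_rois <- function(spec, n_per_dilution = 5, area_fraction = 0.4) {
  tubes <- head_tube_centers(spec)
  roi_d <- spec$tube_diameter * sqrt(area_fraction)
  off <- (spec$tube_diameter - roi_d) / 2 * 0.35
  rois <- list()
  for (dil in c("low", "high")) {
    tt <- tubes[tubes$dilution == dil, ]
    # cycle tubes, stepping the vertical offset: center, +off, -off, ...
    offs <- c(0, off, -off, off / 2, -off / 2)
    for (k in seq_len(n_per_dilution)) {
      tube <- tt[((k - 1) %% nrow(tt)) + 1, ]
      rois[[length(rois) + 1]] <- roi_spec(
        x = tube$x, y = tube$y + offs[((k - 1) %% length(offs)) + 1],
        diameter = roi_d,
        label = sprintf("tube_%s_%d", dil, k)
      )
    }
  }
  rois
}
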
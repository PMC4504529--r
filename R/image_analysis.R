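# Objective image analysis: circular ROI statistics (mean attenuation, SD as
# the noise measure, SNR) and replication of identical ROIs across matched
# dose-series images.

#' Circular region of interest
#'
#' @param x,y ROI center in mm, image coordinates (origin at image center,
#'   x to the right, y up).
#' @param diameter ROI diameter in mm.
#' @param label character label.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(x, y, diameter, label = "roi") {
  if (diameter <= 0) stop("ROI diameter must be positive", call. = FALSE)
  structure(list(x = x, y = y, diameter = diameter, label = label),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> '%s' at (%.1f, %.1f) mm, d = %.1f mm\n",
              x$label, x$x, x$y, x$diameter))
  invisible(x)
}

#' ROI statistics on a reconstructed image
#'
#' Pixels whose centers fall inside the ROI disk are pooled; the mean
#' attenuation (HU) and the standard deviation (HU, `n - 1` denominator,
#' the operational noise measure) are computed, and SNR = mean / SD. A
#' zero-SD (constant) ROI leaves SNR undefined (`NA`) and sets
#' `snr_defined = FALSE`.
#'
#' @param image a [recon_image()].
#' @param roi a [roi_spec()]; must lie fully inside the image.
#' @return one-row data.frame: `label`, `mean`, `sd`, `snr`, `n_pixels`,
#'   `snr_defined`.
#' @export
roi_stats <- function(image, roi) {
  stopifnot(inherits(image, "recon_image"), inherits(roi, "roi_spec"))
  half <- image$fov / 2
  r <- roi$diameter / 2
  if (abs(roi$x) + r > half || abs(roi$y) + r > half)
    stop(sprintf("ROI '%s' extends outside the image", roi$label),
         call. = FALSE)
  n <- nrow(image$grid)
  mask <- disk_mask(n, image$fov, roi$x, roi$y, r)
  px <- image$grid[mask]
  if (length(px) < 2)
    stop(sprintf("ROI '%s' covers fewer than 2 pixels", roi$label),
         call. = FALSE)
  m <- mean(px)
  s <- stats::sd(px)
  defined <- s > 0
  data.frame(
    label = roi$label, mean = m, sd = s,
    snr = if (defined) m / s else NA_real_,
    n_pixels = length(px), snr_defined = defined,
    stringsAsFactors = FALSE
  )
}

#' Union pixel mask of a set of ROIs
#'
#' Builds the logical mask of all pixels covered by any ROI of the set on
#' the given image geometry; pixel-center inclusion, the same rule
#' [roi_stats()] uses, so a reconstruction restricted to this mask yields
#' identical ROI statistics.
#'
#' @param rois list of [roi_spec()].
#' @param grid_size image side in pixels.
#' @param fov image field of view in mm.
#' @return logical `grid_size x grid_size` matrix.
#' @export
roi_mask <- function(rois, grid_size, fov) {
  m <- matrix(FALSE, grid_size, grid_size)
  for (roi in rois)
    m <- m | disk_mask(grid_size, fov, roi$x, roi$y, roi$diameter / 2)
  m
}

#' Replicate ROIs across a matched dose series
#'
#' Applies an identical ROI set to every image of a series (the
#' copy-and-paste replication across matched dose levels): one row per
#' (ROI x image). All images must share grid size and field of view.
#'
#' @param rois list of [roi_spec()].
#' @param series list of [recon_image()]; names (or dose-fraction
#'   provenance) label the `image` column.
#' @return data.frame with columns `image`, `label`, `mean`, `sd`, `snr`,
#'   `n_pixels`, `snr_defined`.
#' @export
replicate_rois <- function(rois, series) {
  stopifnot(length(rois) > 0, length(series) > 0)
  geo <- vapply(series, function(im) c(nrow(im$grid), im$fov), numeric(2))
  if (any(geo[1, ] != geo[1, 1]) || any(geo[2, ] != geo[2, 1]))
    stop("images in the series have mismatched geometry", call. = FALSE)
  nm <- names(series)
  if (is.null(nm)) nm <- as.character(seq_along(series))
  rows <- list()
  for (i in seq_along(series)) {
    for (roi in rois) {
      st <- roi_stats(series[[i]], roi)
      st$image <- nm[i]
      rows[[length(rows) + 1]] <- st
    }
  }
  out <- do.call(rbind, rows)
  out[, c("image", "label", "mean", "sd", "snr", "n_pixels", "snr_defined")]
}
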
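# Serialization: RDS is the native container for image-like objects
# (attenuation maps, sinograms, reconstructions), JSON for specs and noise
# models, CSV for tables, and PNG for windowed image previews.

#' Save / load package objects
#'
#' `write_ct()` saves any package object (attenuation map, sinogram,
#' reconstruction, ledger, report) to an RDS container; `read_ct()` loads
#' it back.
#'
#' @param x object to save.
#' @param path file path (`.rds`).
#' @return `read_ct()` returns the object; `write_ct()` the path,
#'   invisibly.
#' @export
write_ct <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_ct
#' @export
read_ct <- function(path) readRDS(path)

#' Serialize a phantom spec or noise model to JSON
#'
#' @param x a [phantom_spec()] or [noise_model()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_spec_json <- function(x, path) {
  stopifnot(inherits(x, "phantom_spec") || inherits(x, "noise_model"))
  payload <- unclass(x)
  payload$.class <- class(x)[1]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a phantom spec or noise model from JSON
#'
#' @param path JSON path written by [write_spec_json()].
#' @return the restored object.
#' @export
read_spec_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- payload$.class
  payload$.class <- NULL
  if (identical(cls, "phantom_spec")) {
    do.call(phantom_spec, payload)
  } else if (identical(cls, "noise_model")) {
    do.call(noise_model, payload)
  } else {
    stop("unrecognized JSON payload class: ", cls, call. = FALSE)
  }
}

#' Windowed PNG preview of an image
#'
#' Renders an HU image with a display window (default width 700 HU, center
#' 100 HU, the soft-tissue angiography window) to an 8-bit grayscale PNG.
#'
#' @param image a [recon_image()] or [attenuation_map()].
#' @param path output PNG path.
#' @param center,width display window in HU.
#' @return `path`, invisibly.
#' @export
write_png_preview <- function(image, path, center = 100, width = 700) {
  grid <- image$grid
  lo <- center - width / 2
  g <- pmin(pmax((grid - lo) / width, 0), 1)
  png::writePNG(g, path)
  invisible(path)
}
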
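# HistoImage: the in-memory photomicrograph container.
#
# Pixels are stored as a numeric matrix (grayscale) or an nrow x ncol x 3
# array (RGB) with intensities in [0, 1]; `pixel_area` carries the
# physical scale in um^2/pixel (default 0.013, the acquisition resolution
# the analysis is calibrated for).

DEFAULT_PIXEL_AREA <- 0.013

#' Construct a histology image
#'
#' @param pixels Numeric matrix (grayscale) or `nrow x ncol x 3` array (RGB)
#'   with finite intensities in `[0, 1]`.
#' @param pixel_area Physical pixel area in um^2/pixel (default 0.013).
#' @param stain Stain label, one of `"myelin"`, `"nissl"`, `"other"`.
#' @return An object of class `histo_image`.
#' @export
histo_image <- function(pixels, pixel_area = DEFAULT_PIXEL_AREA,
                        stain = c("other", "myelin", "nissl")) {
  stain <- match.arg(stain)
  if (is.matrix(pixels)) {
    dimok <- TRUE
  } else if (is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3) {
    dimok <- TRUE
  } else dimok <- FALSE
  if (!dimok) stop("pixels must be a matrix or an nrow x ncol x 3 array")
  if (!all(is.finite(pixels))) stop("intensities must be finite")
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9) {
    stop("intensities must lie in [0, 1]; normalize on load")
  }
  if (!is.numeric(pixel_area) || length(pixel_area) != 1 || pixel_area <= 0) {
    stop("pixel_area must be a positive scalar (um^2/pixel)")
  }
  structure(list(pixels = pixels, pixel_area = pixel_area, stain = stain),
            class = "histo_image")
}

#' @export
print.histo_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<histo_image> %d x %d %s, stain=%s, pixel_area=%g um^2/px\n",
              d[1], d[2], if (length(d) == 3) "RGB" else "gray",
              x$stain, x$pixel_area))
  invisible(x)
}

is_rgb <- function(img) length(dim(img$pixels)) == 3

#' Convert an RGB histology image to grayscale luminance
#'
#' Uses the luminance weights 0.2125 R + 0.7154 G + 0.0721 B. Grayscale
#' input is returned unchanged.
#'
#' @param img A [histo_image].
#' @return A grayscale matrix in `[0, 1]`.
#' @export
as_gray <- function(img) {
  p <- img$pixels
  if (!is_rgb(img)) return(p)
  0.2125 * p[, , 1] + 0.7154 * p[, , 2] + 0.0721 * p[, , 3]
}

#' HSV value channel of an RGB image
#'
#' The value channel is the per-pixel maximum over R, G, B.
#' @noRd
hsv_value <- function(img) {
  stopifnot(is_rgb(img))
  pmax(img$pixels[, , 1], img$pixels[, , 2], img$pixels[, , 3])
}

#' Load a photomicrograph from TIFF or PNG
#'
#' Intensities are normalized to `[0, 1]` (tiff/png readers already return
#' that scale for 8- and 16-bit data). The pixel area is taken from, in
#' order of precedence: the `pixel_area` argument, a JSON sidecar
#' `<path>.json` with a `pixel_area_um2` entry, or the 0.013 um^2/px
#' default.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_area Optional um^2/pixel override.
#' @param stain Stain label stored on the image.
#' @return A [histo_image].
#' @export
load_image <- function(path, pixel_area = NULL, stain = "other") {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  p <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, " (use TIFF or PNG)")
  )
  if (length(dim(p)) == 3 && dim(p)[3] == 4) p <- p[, , 1:3]  # drop alpha
  if (length(dim(p)) == 3 && dim(p)[3] == 2) p <- p[, , 1]    # gray + alpha
  if (is.null(pixel_area)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      pixel_area <- meta$pixel_area_um2 %||% NULL
    }
  }
  histo_image(p, pixel_area = pixel_area %||% DEFAULT_PIXEL_AREA, stain = stain)
}

#' Save a histology image to TIFF or PNG
#'
#' Writes 16-bit output so a save/load round trip preserves intensities to
#' better than 1/65535; a JSON sidecar records the pixel area.
#'
#' @param img A [histo_image].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @param sidecar Write the `<path>.json` pixel-size sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, sidecar = TRUE) {
  ext <- tolower(tools::file_ext(path))
  p <- pmin(pmax(img$pixels, 0), 1)
  switch(ext,
    tif = , tiff = tiff::writeTIFF(p, path, bits.per.sample = 16),
    png = png::writePNG(p, path),
    stop("unsupported image format: .", ext)
  )
  if (sidecar) {
    jsonlite::write_json(list(pixel_area_um2 = img$pixel_area, stain = img$stain),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Load an ROI mask image
#'
#' Any strictly positive pixel is part of the ROI.
#' @param path TIFF/PNG mask path.
#' @return A logical matrix.
#' @export
load_mask <- function(path) {
  img <- load_image(path)
  m <- as_gray(img)
  m > 0
}
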
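#' Calibrated single-channel image
#'
#' The package's working representation of a photograph: a numeric matrix of
#' intensities in `[0, 1]` plus acquisition metadata. `l_pixel` is the physical
#' edge length of one pixel in millimetres and drives the conversion from pixel
#' counts to physical areas; it is supplied by the user from the original image
#' calibration (scale bar, known object size, ...).
#'
#' @param pixels Numeric matrix with values in `[0, 1]` (rows = image rows).
#' @param l_pixel Physical length per pixel in mm, strictly positive, or `NULL`
#'   when no calibration is available.
#' @param modality One of `"VL"` (visible light), `"IR"` (infrared through a
#'   long-pass filter), `"TAPE_SCAN"`.
#' @param fabric One of `"WHITE_COTTON"`, `"DENIM"`, `"TAPE"`, `"UNKNOWN"`.
#'
#' @return An object of class `gsr_image` with elements `pixels`, `height`,
#'   `width`, `l_pixel`, `modality`, `fabric`.
#' @export
#' @examples
#' img <- gsr_image(matrix(runif(64), 8, 8), l_pixel = 0.1)
#' img$height
gsr_image <- function(pixels, l_pixel = NULL,
                      modality = c("VL", "IR", "TAPE_SCAN"),
                      fabric = c("UNKNOWN", "WHITE_COTTON", "DENIM", "TAPE")) {
  modality <- match.arg(modality)
  fabric <- match.arg(fabric)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("intensities must lie in [0, 1] with no missing values", call. = FALSE)
  }
  check_l_pixel(l_pixel)
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         l_pixel = l_pixel, modality = modality, fabric = fabric),
    class = "gsr_image"
  )
}

check_l_pixel <- function(l_pixel) {
  if (is.null(l_pixel)) return(invisible(NULL))
  if (!is.numeric(l_pixel) || length(l_pixel) != 1L || !is.finite(l_pixel) ||
      l_pixel <= 0) {
    stop("`l_pixel` must be a single strictly positive finite number (mm/pixel)",
         call. = FALSE)
  }
  invisible(NULL)
}

#' RGB colour image
#'
#' @param pixels Numeric array `height x width x 3`, channels R, G, B, each in
#'   `[0, 1]`.
#' @param l_pixel Optional physical length per pixel in mm.
#'
#' @return An object of class `gsr_rgb`.
#' @export
gsr_rgb <- function(pixels, l_pixel = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be a height x width x 3 numeric array", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("channel values must lie in [0, 1] with no missing values",
         call. = FALSE)
  }
  check_l_pixel(l_pixel)
  structure(
    list(pixels = pixels, height = dim(pixels)[1], width = dim(pixels)[2],
         l_pixel = l_pixel),
    class = "gsr_rgb"
  )
}

#' @export
print.gsr_image <- function(x, ...) {
  cal <- if (is.null(x$l_pixel)) "uncalibrated" else
    sprintf("%g mm/pixel", x$l_pixel)
  cat(sprintf("<gsr_image> %d x %d, %s, %s, %s\n",
              x$height, x$width, x$modality, x$fabric, cal))
  invisible(x)
}

#' @export
print.gsr_rgb <- function(x, ...) {
  cat(sprintf("<gsr_rgb> %d x %d x 3\n", x$height, x$width))
  invisible(x)
}

#' Load a raster image from disk
#'
#' Reads PNG, TIFF or JPEG. Integer sample depths (8- or 16-bit) are rescaled
#' to `[0, 1]`. Single-channel files yield a [gsr_image()]; files with three or
#' more channels yield a [gsr_rgb()] (a fourth alpha channel is dropped).
#'
#' @param path Path to a readable PNG/TIFF/JPEG file.
#' @param l_pixel Optional physical length per pixel (mm).
#' @inheritParams gsr_image
#'
#' @return A `gsr_image` or `gsr_rgb`.
#' @export
load_image <- function(path, l_pixel = NULL, modality = "VL",
                       fabric = "UNKNOWN") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop(sprintf("cannot read image file: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  pix <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop(sprintf("unsupported image format '%s' (use PNG, TIFF or JPEG): %s",
                 ext, path), call. = FALSE)
  )
  # readers already rescale integer depths to [0,1]; clamp tiny excursions
  pix <- pmin(pmax(pix, 0), 1)
  if (is.matrix(pix)) {
    gsr_image(pix, l_pixel = l_pixel, modality = modality, fabric = fabric)
  } else if (length(dim(pix)) == 3L && dim(pix)[3] >= 3L) {
    gsr_rgb(pix[, , 1:3, drop = FALSE], l_pixel = l_pixel)
  } else if (length(dim(pix)) == 3L && dim(pix)[3] %in% c(1L, 2L)) {
    # greyscale (+ alpha)
    gsr_image(pix[, , 1], l_pixel = l_pixel, modality = modality,
              fabric = fabric)
  } else {
    stop(sprintf("unrecognised channel layout in %s", path), call. = FALSE)
  }
}

#' Write an intensity image to a 16-bit PNG
#'
#' @param img A [gsr_image()].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(inherits(img, "gsr_image"))
  png::writePNG(img$pixels, target = path)
  invisible(path)
}

#' Convert an RGB image to greyscale luma
#'
#' Uses fixed Rec. 601 weights `0.299 R + 0.587 G + 0.114 B` so the conversion
#' is reproducible across machines (camera "monochrome" modes vary).
#'
#' @param img A [gsr_rgb()].
#' @inheritParams gsr_image
#' @return A [gsr_image()].
#' @export
to_grayscale <- function(img, modality = "VL", fabric = "UNKNOWN") {
  stopifnot(inherits(img, "gsr_rgb"))
  y <- 0.299 * img$pixels[, , 1] + 0.587 * img$pixels[, , 2] +
    0.114 * img$pixels[, , 3]
  y <- matrix(y, img$height, img$width)
  gsr_image(pmin(pmax(y, 0), 1), l_pixel = img$l_pixel,
            modality = modality, fabric = fabric)
}

#' Extract the HSV value channel
#'
#' The value channel of the hexcone HSV model, `V = max(R, G, B)` per pixel.
#' Developed tape lifts are analysed on this channel: the violet lead-reaction
#' spots stay dark in V while the pale tape background stays bright, and V is
#' by construction invariant to hue.
#'
#' @param img A [gsr_rgb()] scan of a developed adhesive tape.
#' @return A [gsr_image()] with modality `"TAPE_SCAN"` and fabric `"TAPE"`.
#' @export
value_channel <- function(img) {
  stopifnot(inherits(img, "gsr_rgb"))
  v <- pmax(img$pixels[, , 1], img$pixels[, , 2], img$pixels[, , 3])
  v <- matrix(v, img$height, img$width)
  gsr_image(v, l_pixel = img$l_pixel, modality = "TAPE_SCAN", fabric = "TAPE")
}
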
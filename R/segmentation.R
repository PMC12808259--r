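#' Binary particle mask
#'
#' @param pixels Logical matrix, `TRUE` = foreground (candidate particle).
#' @param connectivity Neighbourhood used when labelling, 4 or 8.
#' @return An object of class `gsr_mask`.
#' @export
gsr_mask <- function(pixels, connectivity = 8) {
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    stop("`pixels` must be a logical matrix", call. = FALSE)
  }
  if (anyNA(pixels)) stop("mask must not contain NA", call. = FALSE)
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  structure(list(pixels = pixels, connectivity = as.integer(connectivity)),
            class = "gsr_mask")
}

#' @export
print.gsr_mask <- function(x, ...) {
  cat(sprintf("<gsr_mask> %d x %d, %d foreground px, %d-connectivity\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels), x$connectivity))
  invisible(x)
}

#' Segment dark spots by intensity threshold
#'
#' Foreground ("white areas" of the segmented image) are the pixels strictly
#' darker than the threshold. With `threshold = "auto"` the threshold is chosen
#' by Otsu's between-class-variance criterion on a 256-bin intensity histogram;
#' fabrics with atypical contrast can override it with a manual value.
#'
#' Because filtered images are re-normalized to full scale, an image that
#' contains no residue at all presents Otsu with nothing but stretched noise,
#' whose "dark class" would cover about half the frame. AUTO therefore treats
#' its split as valid only if the resulting foreground stays below
#' `max_dark_fraction` of the pixels — residue plausibly covers a small
#' minority of a photograph — and returns an empty mask otherwise. Manual
#' thresholds are always honoured as given.
#'
#' @param img A [gsr_image()], normally the output of
#'   [apply_frequency_filter()] or [value_channel()].
#' @param threshold Intensity in `[0, 1]`, or `"auto"` for Otsu.
#' @param connectivity Connectivity recorded on the mask for later labelling.
#' @param max_dark_fraction Plausibility bound on the AUTO foreground
#'   fraction; ignored for manual thresholds.
#' @return A [gsr_mask()]; the threshold actually used is attached as attribute
#'   `"threshold"` (0 when the AUTO guard rejected the split).
#' @export
threshold_dark <- function(img, threshold = "auto", connectivity = 8,
                           max_dark_fraction = 0.25) {
  stopifnot(inherits(img, "gsr_image"))
  if (identical(threshold, "auto") || identical(threshold, "AUTO")) {
    threshold <- if (diff(range(img$pixels)) < .Machine$double.eps * 16) {
      0 # constant image: nothing is a dark outlier
    } else {
      otsu_threshold(img$pixels)
    }
    if (mean(img$pixels < threshold) > max_dark_fraction) threshold <- 0
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    stop("`threshold` must be \"auto\" or a number in [0, 1]", call. = FALSE)
  }
  m <- gsr_mask(img$pixels < threshold, connectivity = connectivity)
  attr(m, "threshold") <- threshold
  m
}

#' Otsu threshold of an intensity matrix
#'
#' Maximizes between-class variance over a 256-level histogram on `[0, 1]`
#' (computed by [EBImage::otsu()]).
#'
#' @param pixels Numeric matrix in `[0, 1]`.
#' @return The threshold, a number in `[0, 1]`.
#' @export
otsu_threshold <- function(pixels) {
  as.numeric(EBImage::otsu(EBImage::Image(pixels), range = c(0, 1),
                           levels = 256))
}

#' Label connected foreground regions as particles
#'
#' Every maximal connected foreground region under the mask's connectivity
#' becomes one particle, with its pixel count, centroid, bounding box and —
#' when a calibration is supplied — physical area.
#'
#' @param mask A [gsr_mask()].
#' @param l_pixel Optional physical length per pixel (mm); when given, each
#'   particle's `area_mm2 = l_pixel^2 * n_pixel`.
#' @param provenance Optional named list recorded on the result (filter,
#'   threshold, ...).
#' @return A `gsr_particles` tibble with one row per particle: `label`,
#'   `n_pixel`, `centroid_row`, `centroid_col`, `row_min`, `col_min`,
#'   `row_max`, `col_max` (half-open bounds) and optionally `area_mm2`.
#'   Attributes: `connectivity`, `n_foreground`, `l_pixel`, `provenance`.
#' @export
label_components <- function(mask, l_pixel = NULL, provenance = list()) {
  stopifnot(inherits(mask, "gsr_mask"))
  check_l_pixel(l_pixel)
  lab <- .label_cc(mask$pixels, mask$connectivity)
  idx <- which(lab > 0L)
  labs <- lab[idx]
  if (length(idx) == 0L) {
    tab <- tibble::tibble(
      label = integer(), n_pixel = integer(),
      centroid_row = numeric(), centroid_col = numeric(),
      row_min = integer(), col_min = integer(),
      row_max = integer(), col_max = integer()
    )
  } else {
    rows <- ((idx - 1L) %% nrow(lab)) + 1L
    cols <- ((idx - 1L) %/% nrow(lab)) + 1L
    n <- tabulate(labs)
    tab <- tibble::tibble(
      label = seq_along(n),
      n_pixel = n,
      centroid_row = as.numeric(rowsum(rows, labs)) / n,
      centroid_col = as.numeric(rowsum(cols, labs)) / n,
      row_min = as.integer(tapply(rows, labs, min)),
      col_min = as.integer(tapply(cols, labs, min)),
      row_max = as.integer(tapply(rows, labs, max)) + 1L,
      col_max = as.integer(tapply(cols, labs, max)) + 1L
    )
  }
  if (!is.null(l_pixel)) tab$area_mm2 <- l_pixel^2 * tab$n_pixel
  new_particles(tab, connectivity = mask$connectivity,
                n_foreground = length(idx), l_pixel = l_pixel,
                provenance = provenance, label_matrix = lab)
}

new_particles <- function(tab, connectivity, n_foreground, l_pixel,
                          provenance, label_matrix = NULL) {
  structure(tab,
            class = c("gsr_particles", class(tibble::tibble()))) -> out
  attr(out, "connectivity") <- connectivity
  attr(out, "n_foreground") <- n_foreground
  attr(out, "l_pixel") <- l_pixel
  attr(out, "provenance") <- provenance
  attr(out, "label_matrix") <- label_matrix
  out
}

#' Drop particles below a minimum pixel count
#'
#' Isolated dark pixels at these imaging scales are sensor noise or stray
#' fabric fibres rather than residue particles; a small size floor removes
#' them. Survivor order and labels are preserved.
#'
#' @param particles A `gsr_particles` table from [label_components()].
#' @param min_pixels Minimum `n_pixel` to keep, `>= 1` (1 = keep everything).
#' @return A filtered `gsr_particles` table; `n_foreground` is updated to the
#'   surviving pixel total.
#' @export
filter_small <- function(particles, min_pixels = 2) {
  stopifnot(inherits(particles, "gsr_particles"))
  if (!is.numeric(min_pixels) || length(min_pixels) != 1L ||
      is.na(min_pixels) || min_pixels < 1) {
    stop("`min_pixels` must be a single integer >= 1", call. = FALSE)
  }
  keep <- particles$n_pixel >= min_pixels
  out <- particles[keep, ]
  prov <- attr(particles, "provenance")
  prov$min_pixels <- min_pixels
  new_particles(tibble::as_tibble(out),
                connectivity = attr(particles, "connectivity"),
                n_foreground = sum(out$n_pixel),
                l_pixel = attr(particles, "l_pixel"),
                provenance = prov,
                label_matrix = attr(particles, "label_matrix"))
}
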
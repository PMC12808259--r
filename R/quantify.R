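#' Physical particle area from pixel count
#'
#' Converts a pixel count to a physical area through the image calibration:
#' `A = l_pixel^2 * n_pixel`, where `l_pixel` is the physical edge length of a
#' pixel in mm and `n_pixel` the number of foreground pixels of the particle.
#' Vectorized over `n_pixel`.
#'
#' @param n_pixel Integer pixel count(s), `>= 0`.
#' @param l_pixel Physical length per pixel (mm), `> 0`.
#' @return Area(s) in mm^2.
#' @export
#' @examples
#' particle_area(25, l_pixel = 0.1) # 0.25 mm^2
particle_area <- function(n_pixel, l_pixel) {
  if (!is.numeric(n_pixel) || anyNA(n_pixel) || any(n_pixel < 0)) {
    stop("`n_pixel` must be non-negative", call. = FALSE)
  }
  check_l_pixel(l_pixel)
  l_pixel^2 * n_pixel
}

#' Summarize a particle set into the two primary quantities
#'
#' Reduces a labelled particle table to the count and the total area of
#' detected residue, the headline quantities of the analysis. Area is reported
#' both in pixels and — when a calibration is known — in mm^2.
#'
#' @param particles A `gsr_particles` table.
#' @param l_pixel Optional calibration override (mm/pixel); defaults to the
#'   value carried by the particle table.
#' @return An object of class `gsr_quant` with elements `count`,
#'   `total_pixels`, `total_area_pixels` (alias of `total_pixels`),
#'   `total_area_mm2` (or `NA`), `particles`, `provenance`.
#' @export
summarize_particles <- function(particles, l_pixel = NULL) {
  stopifnot(inherits(particles, "gsr_particles"))
  if (is.null(l_pixel)) l_pixel <- attr(particles, "l_pixel")
  check_l_pixel(l_pixel)
  total <- sum(particles$n_pixel)
  structure(
    list(
      count = nrow(particles),
      total_pixels = total,
      total_area_pixels = total,
      total_area_mm2 = if (is.null(l_pixel)) NA_real_ else
        particle_area(total, l_pixel),
      l_pixel = l_pixel,
      particles = particles,
      provenance = attr(particles, "provenance")
    ),
    class = "gsr_quant"
  )
}

#' @export
print.gsr_quant <- function(x, ...) {
  cat(sprintf("<gsr_quant> %d particles, %d foreground pixels", x$count,
              x$total_pixels))
  if (!is.na(x$total_area_mm2)) cat(sprintf(" (%.4g mm^2)", x$total_area_mm2))
  cat("\n")
  if (length(x$provenance)) {
    pv <- x$provenance
    flt <- if (is.null(pv$filter)) "none" else pv$filter$kind
    cat(sprintf("  filter = %s, threshold = %s, min_pixels = %s, connectivity = %s\n",
                flt,
                if (is.null(pv$threshold)) "?" else format(pv$threshold, digits = 4),
                if (is.null(pv$min_pixels)) "?" else pv$min_pixels,
                if (is.null(pv$connectivity)) "?" else pv$connectivity))
  }
  invisible(x)
}

#' Per-fabric segmentation presets
#'
#' Bundles the filter, threshold rule, size floor and connectivity used by
#' [run_fabric_pipeline()] for each supported trace carrier. Presets are data:
#' override any element per sample (the segmentation of real fabrics often
#' needs individual adjustment of threshold and filter band).
#'
#' @param fabric `"WHITE_COTTON"`, `"DENIM"` or `"TAPE"`.
#' @return A list with elements `filter` (a [filter_spec()] or `NULL`),
#'   `threshold` (`"auto"` or a number), `min_pixels`, `connectivity`.
#' @export
fabric_preset <- function(fabric) {
  base <- list(threshold = "auto", min_pixels = 2, connectivity = 8)
  switch(fabric,
    WHITE_COTTON = c(list(filter = filter_preset("WHITE_COTTON")), base),
    DENIM = c(list(filter = filter_preset("DENIM")), base),
    TAPE = c(list(filter = NULL), base),
    stop(sprintf("no preset for fabric '%s'; pass an explicit config",
                 fabric), call. = FALSE)
  )
}

resolve_config <- function(fabric, config) {
  preset <- tryCatch(fabric_preset(fabric), error = function(e) NULL)
  if (is.null(preset)) {
    if (is.null(config$filter)) {
      stop(sprintf(
        "unknown fabric '%s' and no explicit filter configured", fabric),
        call. = FALSE)
    }
    preset <- list(filter = NULL, threshold = "auto", min_pixels = 2,
                   connectivity = 8)
  }
  utils::modifyList(preset, config, keep.null = TRUE)
}

crop_roi <- function(img, roi) {
  if (is.null(roi)) return(img)
  stopifnot(length(roi) == 4L)
  gsr_image(img$pixels[roi[1]:roi[3], roi[2]:roi[4], drop = FALSE],
            l_pixel = img$l_pixel, modality = img$modality,
            fabric = img$fabric)
}

#' End-to-end fabric pipeline: filter, threshold, label, size-filter, count
#'
#' Runs the complete quantification on a fabric photograph: the fabric's
#' frequency filter (high-pass on white cotton, band-pass on denim), dark-spot
#' thresholding, connected-component labelling, the small-particle floor, and
#' summarization. Every parameter used is recorded in the result's provenance.
#'
#' @param img A [gsr_image()]; its `fabric` metadata selects the preset unless
#'   `config` overrides it.
#' @param config Named list overriding any of `filter` ([filter_spec()] or
#'   `NULL` to skip filtering), `threshold`, `min_pixels`, `connectivity`,
#'   `roi` (`c(row_min, col_min, row_max, col_max)`, inclusive).
#' @return A `gsr_quant` summary.
#' @export
run_fabric_pipeline <- function(img, config = list()) {
  if (inherits(img, "gsr_rgb")) {
    stop("colour input: convert with to_grayscale() or use run_tape_pipeline()",
         call. = FALSE)
  }
  stopifnot(inherits(img, "gsr_image"))
  cfg <- resolve_config(img$fabric, config)
  img <- crop_roi(img, cfg$roi)
  work <- if (is.null(cfg$filter)) img else
    apply_frequency_filter(img, cfg$filter)
  mask <- threshold_dark(work, threshold = cfg$threshold,
                         connectivity = cfg$connectivity,
                         max_dark_fraction = cfg$max_dark_fraction %||% 0.25)
  prov <- list(filter = cfg$filter, threshold = attr(mask, "threshold"),
               min_pixels = cfg$min_pixels, connectivity = cfg$connectivity,
               modality = img$modality, fabric = img$fabric, route = "fabric")
  ps <- label_components(mask, l_pixel = img$l_pixel, provenance = prov)
  ps <- filter_small(ps, min_pixels = cfg$min_pixels)
  summarize_particles(ps)
}

#' End-to-end tape pipeline: value channel, threshold, label, count
#'
#' Quantifies a scanned, chemically developed adhesive tape lift. The RGB scan
#' is reduced to the HSV value channel (hue-invariant, so the violet colour of
#' the lead reaction does not matter), then thresholded and counted like a
#' fabric image, without frequency filtering (tape backgrounds are nearly
#' uniform).
#'
#' @param img A [gsr_rgb()] scan.
#' @param config As in [run_fabric_pipeline()].
#' @return A `gsr_quant` summary; provenance records the HSV route.
#' @export
run_tape_pipeline <- function(img, config = list()) {
  if (inherits(img, "gsr_image")) {
    stop("greyscale input: use run_fabric_pipeline() for single-channel images",
         call. = FALSE)
  }
  stopifnot(inherits(img, "gsr_rgb"))
  v <- value_channel(img)
  cfg <- resolve_config("TAPE", config)
  v <- crop_roi(v, cfg$roi)
  work <- if (is.null(cfg$filter)) v else apply_frequency_filter(v, cfg$filter)
  mask <- threshold_dark(work, threshold = cfg$threshold,
                         connectivity = cfg$connectivity,
                         max_dark_fraction = cfg$max_dark_fraction %||% 0.25)
  prov <- list(filter = cfg$filter, threshold = attr(mask, "threshold"),
               min_pixels = cfg$min_pixels, connectivity = cfg$connectivity,
               modality = "TAPE_SCAN", fabric = "TAPE",
               route = "hsv_value_channel")
  ps <- label_components(mask, l_pixel = v$l_pixel, provenance = prov)
  ps <- filter_small(ps, min_pixels = cfg$min_pixels)
  summarize_particles(ps)
}

#' Match detections to ground truth and score detection F1
#'
#' Used to validate the pipeline on synthetic scenes. A detection matches a
#' true particle when its centroid falls within the particle's radius + 1 px;
#' pairs are matched one-to-one greedily by increasing centroid distance.
#'
#' @param detected A `gsr_particles` table (or `gsr_quant`).
#' @param truth A `scene_truth` object from the synthetic generator, or a data
#'   frame with columns `row`, `col`, `radius`.
#' @return A list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
detection_score <- function(detected, truth) {
  if (inherits(detected, "gsr_quant")) detected <- detected$particles
  if (inherits(truth, "scene_truth")) truth <- truth$particles
  n_det <- nrow(detected)
  n_tru <- nrow(truth)
  if (n_det == 0L || n_tru == 0L) {
    tp <- 0L
  } else {
    d2 <- outer(detected$centroid_row, truth$row, `-`)^2 +
      outer(detected$centroid_col, truth$col, `-`)^2
    lim2 <- matrix((truth$radius + 1)^2, n_det, n_tru, byrow = TRUE)
    cand <- which(d2 <= lim2, arr.ind = TRUE)
    tp <- 0L
    if (nrow(cand) > 0L) {
      ord <- order(d2[cand])
      used_det <- logical(n_det)
      used_tru <- logical(n_tru)
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_det[i] && !used_tru[j]) {
          used_det[i] <- TRUE; used_tru[j] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- n_det - tp
  fn <- n_tru - tp
  prec <- if (n_det > 0) tp / n_det else NA_real_
  rec <- if (n_tru > 0) tp / n_tru else NA_real_
  f1 <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1)
}
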
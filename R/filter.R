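#' Frequency-domain filter specification
#'
#' Describes a radially symmetric filter in the 2-D Fourier domain. Cutoffs are
#' expressed in cycles per image, so a preset transfers across resolutions: a
#' feature repeating `f` times across the frame sits at radius `f` regardless
#' of pixel count.
#'
#' A high-pass filter removes low-frequency content (illumination gradients,
#' coarse fabric pattern); a band-pass additionally removes high-frequency
#' content (fine weave periodicity), keeping only the particle-scale band.
#'
#' @param kind `"high_pass"` or `"band_pass"`.
#' @param low_cut Lower cutoff radius, cycles per image, `> 0`.
#' @param high_cut Upper cutoff radius (band-pass only), `> low_cut`.
#' @param transition_width Width of the Gaussian-edged transition in frequency
#'   units; `0` gives an ideal (hard-edged) filter. Smooth edges limit spatial
#'   ringing and are the default in the fabric presets.
#'
#' @return An object of class `filter_spec`.
#' @export
#' @examples
#' filter_spec("high_pass", low_cut = 8, transition_width = 4)
#' filter_spec("band_pass", low_cut = 6, high_cut = 110, transition_width = 4)
filter_spec <- function(kind = c("high_pass", "band_pass"), low_cut,
                        high_cut = NULL, transition_width = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(low_cut) || length(low_cut) != 1L || !is.finite(low_cut) ||
      low_cut <= 0) {
    stop("`low_cut` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(transition_width) || length(transition_width) != 1L ||
      !is.finite(transition_width) || transition_width < 0) {
    stop("`transition_width` must be >= 0", call. = FALSE)
  }
  if (kind == "band_pass") {
    if (is.null(high_cut) || !is.numeric(high_cut) || length(high_cut) != 1L ||
        !is.finite(high_cut) || high_cut <= low_cut) {
      stop("band-pass requires `high_cut` > `low_cut`", call. = FALSE)
    }
  } else if (!is.null(high_cut)) {
    stop("`high_cut` only applies to band-pass filters", call. = FALSE)
  }
  structure(
    list(kind = kind, low_cut = low_cut, high_cut = high_cut,
         transition_width = transition_width),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  if (x$kind == "high_pass") {
    cat(sprintf("<filter_spec> high-pass, low_cut = %g, transition = %g\n",
                x$low_cut, x$transition_width))
  } else {
    cat(sprintf("<filter_spec> band-pass, [%g, %g], transition = %g\n",
                x$low_cut, x$high_cut, x$transition_width))
  }
  invisible(x)
}

# Centered radial frequency (cycles per image) of every bin of an unshifted
# h x w DFT grid: along each axis frequencies run 0, 1, ..., floor(n/2),
# -(n - floor(n/2) - 1), ..., -1.
freq_radius <- function(height, width) {
  fu <- 0:(height - 1L)
  fu <- ifelse(fu > height / 2, fu - height, fu)
  fv <- 0:(width - 1L)
  fv <- ifelse(fv > width / 2, fv - width, fv)
  sqrt(outer(fu^2, fv^2, `+`))
}

# Gaussian-edged unit step: 0 -> 1 rising through `edge` over scale `tw`.
soft_step <- function(r, edge, tw) {
  if (tw == 0) (r > edge) * 1 else stats::pnorm((r - edge) / tw)
}

#' Build the frequency mask for a filter
#'
#' Returns the real-valued mask in `[0, 1]` over the unshifted DFT grid (DC at
#' element `[1, 1]`). The mask is radially symmetric in centred-frequency
#' coordinates; the DC bin is forced to exactly 0 so filtered output is always
#' mean-free.
#'
#' @param height,width Grid dimensions, `>= 2`.
#' @param spec A [filter_spec()].
#' @return A `height x width` numeric matrix in `[0, 1]`.
#' @export
make_filter_mask <- function(height, width, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (height < 2L || width < 2L) {
    stop("mask requires height and width >= 2", call. = FALSE)
  }
  r <- freq_radius(height, width)
  m <- soft_step(r, spec$low_cut, spec$transition_width)
  if (spec$kind == "band_pass") {
    m <- m * (1 - soft_step(r, spec$high_cut, spec$transition_width))
  }
  m[1, 1] <- 0
  m
}

#' Apply a Fourier-domain filter to an image
#'
#' Forward 2-D FFT, pointwise multiplication by the filter mask, inverse FFT;
#' the (numerically tiny) imaginary residue is discarded. By default the real
#' part is then affinely re-normalized to `[0, 1]` (min to 0, max to 1) so that
#' downstream thresholds work on a common scale; a constant pre-normalization
#' result maps to all zeros. Metadata is preserved.
#'
#' @param img A [gsr_image()] with at least 2 rows and 2 columns.
#' @param spec A [filter_spec()].
#' @param renormalize If `FALSE`, return the raw filtered matrix (mean-free for
#'   any mask with a zero DC bin) instead of a re-normalized `gsr_image`.
#' @return A `gsr_image` (or a plain matrix when `renormalize = FALSE`).
#' @export
apply_frequency_filter <- function(img, spec, renormalize = TRUE) {
  stopifnot(inherits(img, "gsr_image"))
  if (img$height < 2L || img$width < 2L) {
    stop("frequency filtering needs at least a 2 x 2 image", call. = FALSE)
  }
  mask <- make_filter_mask(img$height, img$width, spec)
  ft <- stats::fft(img$pixels)
  out <- Re(stats::fft(ft * mask, inverse = TRUE)) / (img$height * img$width)
  if (!renormalize) return(out)
  rng <- range(out)
  pix <- if (diff(rng) < .Machine$double.eps * 16) {
    matrix(0, img$height, img$width)
  } else {
    (out - rng[1]) / diff(rng)
  }
  res <- gsr_image(pix, l_pixel = img$l_pixel, modality = img$modality,
                   fabric = img$fabric)
  attr(res, "filter") <- spec
  res
}

#' Per-fabric filter presets
#'
#' Default frequency filters for the supported trace carriers. White cotton
#' only needs its illumination gradient and coarse structure removed
#' (high-pass); denim additionally needs its fine twill periodicity suppressed
#' (band-pass). Cutoffs are tunable defaults validated on the synthetic scene
#' suite, not measured constants; override them per sample when fabrics
#' deviate.
#'
#' @param fabric `"WHITE_COTTON"` or `"DENIM"`.
#' @return A [filter_spec()].
#' @export
filter_preset <- function(fabric) {
  switch(fabric,
    WHITE_COTTON = filter_spec("high_pass", low_cut = 8, transition_width = 4),
    DENIM = filter_spec("band_pass", low_cut = 6, high_cut = 110,
                        transition_width = 4),
    stop(sprintf("no filter preset for fabric '%s'; supply one explicitly",
                 fabric), call. = FALSE)
  )
}
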
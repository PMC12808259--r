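#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-particle table of a quantification result
#'
#' @param x A `gsr_quant` result.
#' @param ... Unused.
#' @return A tibble with one row per detected particle.
#' @method tidy gsr_quant
#' @export
tidy.gsr_quant <- function(x, ...) {
  tibble::as_tibble(x$particles)
}

#' One-row summary of a quantification result
#'
#' @param x A `gsr_quant` result.
#' @param ... Unused.
#' @return A one-row tibble: `count`, `total_pixels`, `total_area_mm2`,
#'   `threshold`, `min_pixels`, `connectivity`, `filter`.
#' @method glance gsr_quant
#' @export
glance.gsr_quant <- function(x, ...) {
  pv <- x$provenance
  tibble::tibble(
    count = x$count,
    total_pixels = x$total_pixels,
    total_area_mm2 = x$total_area_mm2,
    threshold = if (is.null(pv$threshold)) NA_real_ else pv$threshold,
    min_pixels = if (is.null(pv$min_pixels)) NA_integer_ else
      as.integer(pv$min_pixels),
    connectivity = if (is.null(pv$connectivity)) NA_integer_ else
      as.integer(pv$connectivity),
    filter = if (is.null(pv$filter)) "none" else pv$filter$kind
  )
}

#' @method tidy gsr_icc
#' @export
tidy.gsr_icc <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, category = as.character(x$category), model = x$model,
    ms_rows = x$ms_rows, ms_cols = x$ms_cols, ms_error = x$ms_error
  )
}

#' @method glance gsr_icc
#' @export
glance.gsr_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, category = as.character(x$category),
                 n_subjects = x$n_subjects, k_raters = x$k_raters)
}

#' @method tidy gsr_ttest
#' @export
tidy.gsr_ttest <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_a - x$mean_b, t = x$t, df = x$df, p.value = x$p,
    significant = x$significant, variant = x$variant
  )
}

#' @method glance gsr_ttest
#' @export
glance.gsr_ttest <- function(x, ...) tidy(x)
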
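#' Ordinal visibility ratings, subjects x raters
#'
#' Holds the manual visibility assessments: each of `n` images (subjects) is
#' scored by each of `k` raters on the 0-5 scale (0 = no residue visible,
#' 5 = substantial).
#'
#' @param values Integer matrix or data frame, rows = subjects, columns =
#'   raters, all entries in 0..5, no missing cells.
#' @return An object of class `rating_matrix` (an integer matrix with subject
#'   and rater dimnames).
#' @export
rating_matrix <- function(values) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("rating matrix must have no missing cells", call. = FALSE)
  if (any(m != round(m)) || any(m < 0) || any(m > 5)) {
    stop("ratings must be integers in 0..5", call. = FALSE)
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("subject_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("rater_", seq_len(ncol(m)))
  structure(m, class = c("rating_matrix", "matrix", "array"))
}

#' Read a rating table from CSV
#'
#' Expects rows = images/subjects and columns = raters, integer cells 0-5. A
#' first non-numeric column is treated as subject identifiers.
#'
#' @param path CSV file path.
#' @return A [rating_matrix()].
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) > 1L && !is.numeric(df[[1]])) {
    rn <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
    rownames(df) <- rn
  }
  rating_matrix(df)
}

# verbal anchors of the 0-5 visibility scale
rating_levels <- c(none_visible = 0L, minimal = 1L, slight = 2L, moderate = 3L,
                   considerable = 4L, substantial = 5L)

#' Encode a verbal visibility label as its 0-5 score
#'
#' @param label Character vector of labels among `none_visible`, `minimal`,
#'   `slight`, `moderate`, `considerable`, `substantial`.
#' @return Integer score(s) 0-5.
#' @export
#' @examples
#' encode_rating(c("none_visible", "moderate", "substantial")) # 0 3 5
encode_rating <- function(label) {
  out <- rating_levels[match(label, names(rating_levels))]
  if (anyNA(out)) {
    bad <- unique(label[is.na(out)])
    stop(sprintf("unknown rating label(s): %s (expected %s)",
                 paste(bad, collapse = ", "),
                 paste(names(rating_levels), collapse = ", ")), call. = FALSE)
  }
  unname(out)
}

#' Intraclass correlation, two-way mixed model, single measures
#'
#' Inter-rater agreement for a fixed set of raters each scoring every subject
#' once: the Shrout-Fleiss ICC(3,1) consistency coefficient,
#' `(MS_rows - MS_error) / (MS_rows + (k - 1) MS_error)`, where the mean
#' squares come from the two-way subjects x raters ANOVA with the interaction
#' as error. Consistency means a constant offset between raters does not lower
#' agreement. The absolute-agreement variant ICC(2,1), which does penalize
#' rater offsets, is available for sensitivity analysis.
#'
#' @param m A [rating_matrix()] or numeric matrix (rows = subjects, columns =
#'   raters), no missing cells.
#' @param type `"consistency"` (ICC(3,1), default) or `"agreement"`
#'   (ICC(2,1)).
#' @return An object of class `gsr_icc`: `icc`, `model`, `category` (via
#'   [classify_icc()]), `ms_rows`, `ms_cols`, `ms_error`, `n_subjects`,
#'   `k_raters`.
#' @export
icc_two_way_mixed_single <- function(m, type = c("consistency", "agreement")) {
  type <- match.arg(type)
  m <- as.matrix(m)
  if (anyNA(m)) stop("rating matrix must have no missing cells", call. = FALSE)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  }
  n <- nrow(m); k <- ncol(m)
  if (stats::var(as.vector(m)) == 0) {
    stop("ICC is undefined for a constant rating matrix (zero total variance)",
         call. = FALSE)
  }
  df <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  fit <- stats::aov(y ~ subject + rater, data = df)
  tab <- summary(fit)[[1]]
  ms <- tab[["Mean Sq"]]
  names(ms) <- trimws(rownames(tab))
  msr <- ms[["subject"]]
  msc <- ms[["rater"]]
  mse <- ms[["Residuals"]]
  icc <- if (type == "consistency") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  }
  model <- if (type == "consistency") {
    "two-way mixed, single measures, consistency (ICC(3,1))"
  } else {
    "two-way random, single measures, absolute agreement (ICC(2,1))"
  }
  structure(
    list(icc = icc, model = model, category = classify_icc(icc),
         ms_rows = msr, ms_cols = msc, ms_error = mse,
         n_subjects = n, k_raters = k),
    class = "gsr_icc"
  )
}

#' @export
print.gsr_icc <- function(x, ...) {
  cat(sprintf("ICC = %.4f (%s)\n%s\n%d subjects, %d raters\n",
              x$icc, x$category, x$model, x$n_subjects, x$k_raters))
  invisible(x)
}

#' Classify an ICC value into an agreement band
#'
#' Bands: excellent for `icc >= 0.75`, good for `[0.60, 0.75)`, fair for
#' `[0.40, 0.60)`, poor below 0.40. The conventional fair and good bands
#' overlap in print (0.4-0.69 vs 0.6-0.74); this implementation places the
#' single-valued boundary at 0.60, the good band's lower edge.
#'
#' @param icc Numeric value(s), each `<= 1`.
#' @return Factor with levels poor < fair < good < excellent.
#' @export
#' @examples
#' classify_icc(c(0.47, 0.76)) # fair, excellent
classify_icc <- function(icc) {
  if (any(icc > 1 + 1e-12, na.rm = TRUE)) {
    stop("ICC cannot exceed 1", call. = FALSE)
  }
  cut(icc, breaks = c(-Inf, 0.40, 0.60, 0.75, 1),
      labels = c("poor", "fair", "good", "excellent"), right = FALSE,
      include.lowest = TRUE)
}

#' Independent-samples t-test
#'
#' Two-sided test for a mean difference between two independent groups at
#' significance level 0.05. `"student"` pools the variances
#' (df = n_a + n_b - 2); `"welch"` uses the Welch-Satterthwaite degrees of
#' freedom and does not assume equal variances.
#'
#' @param a,b Numeric samples, each of length `>= 2`.
#' @param variant `"student"` (default) or `"welch"`.
#' @param alpha Significance level for the `significant` flag.
#' @return An object of class `gsr_ttest`: `t`, `df`, `p`, `significant`,
#'   `variant`, `mean_a`, `mean_b`, `alpha`.
#' @export
independent_t_test <- function(a, b, variant = c("student", "welch"),
                               alpha = 0.05) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      # degenerate but well-defined: no difference at all
      df <- if (variant == "student") length(a) + length(b) - 2 else NA_real_
      res <- list(t = 0, df = df, p = 1)
    } else {
      stop("both samples are constant with different means: t is infinite",
           call. = FALSE)
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = (variant == "student"),
                        alternative = "two.sided")
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  structure(
    list(t = res$t, df = res$df, p = res$p,
         significant = res$p < alpha, variant = variant,
         mean_a = mean(a), mean_b = mean(b), alpha = alpha),
    class = "gsr_ttest"
  )
}

#' @export
print.gsr_ttest <- function(x, ...) {
  cat(sprintf("independent samples t-test (%s): t = %.4f, df = %.2f, p = %.4g%s\n",
              x$variant, x$t, x$df, x$p,
              if (x$significant) sprintf(" (significant at %.2g)", x$alpha)
              else ""))
  invisible(x)
}
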
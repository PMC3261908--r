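#' Fit a line of equivalence to paired fluorescence measurements
#'
#' Ordinary least-squares affine fit `y = a + s * x` to paired input/output
#' fluorescence readings taken at matched inducer levels. The slope `s` is
#' the input-to-output scale factor (ratio of translation rates in the two
#' channels' fluorescence units); backgrounds are derived from the fit and,
#' where available, the zero-inducer readings: `b_x` is the mean `x` at the
#' lowest inducer level (or the minimum `x` if no inducer column is
#' present), and `b_y = a + s * b_x`, so that after background subtraction
#' the line passes through the origin with slope `s`.
#'
#' @param pairs Data frame with numeric columns `x` and `y` (>= 3 rows);
#'   an optional `IPTG_uM` (or `inducer`) column identifies the
#'   zero-inducer readings used for `b_x`.
#' @return An object of class `equivalence_line` with fields `scale`,
#'   `background_x`, `background_y`, `intercept`, `residual_sd`, `n`.
#' @export
fit_equivalence_line <- function(pairs) {
  if (!all(c("x", "y") %in% names(pairs)))
    stop("pairs must have columns x and y", call. = FALSE)
  pairs <- pairs[is.finite(pairs$x) & is.finite(pairs$y), , drop = FALSE]
  if (nrow(pairs) < 3)
    stop("need >= 3 (x, y) pairs for an affine fit", call. = FALSE)
  if (stats::sd(pairs$x) == 0)
    stop("degenerate calibration: x values are all equal", call. = FALSE)
  fit <- stats::lm(y ~ x, data = pairs)
  s <- unname(stats::coef(fit)[2])
  a <- unname(stats::coef(fit)[1])
  if (!is.finite(s) || s <= 0)
    stop("fitted scale factor is not positive; channels appear miscalibrated",
         call. = FALSE)
  ind_col <- intersect(c("IPTG_uM", "inducer"), names(pairs))
  b_x <- if (length(ind_col)) {
    lo <- pairs[[ind_col[1]]] == min(pairs[[ind_col[1]]])
    mean(pairs$x[lo])
  } else {
    min(pairs$x)
  }
  b_y <- a + s * b_x
  structure(list(
    scale = s,
    background_x = max(b_x, 0),
    background_y = max(b_y, 0),
    intercept = a,
    residual_sd = stats::sigma(fit),
    n = nrow(pairs)
  ), class = "equivalence_line")
}

#' Construct a line of equivalence from known constants
#'
#' @param scale Input-to-output scale factor `s` (> 0).
#' @param background_x,background_y Channel backgrounds (>= 0).
#' @return An `equivalence_line`.
#' @export
equivalence_line <- function(scale, background_x = 0, background_y = 0) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0", call. = FALSE)
  if (background_x < 0 || background_y < 0)
    stop("backgrounds must be >= 0", call. = FALSE)
  structure(list(scale = scale, background_x = background_x,
                 background_y = background_y,
                 intercept = background_y - scale * background_x,
                 residual_sd = NA_real_, n = NA_integer_),
            class = "equivalence_line")
}

#' @export
print.equivalence_line <- function(x, ...) {
  cat("Line of equivalence\n")
  cat(sprintf("  scale factor s: %.5g\n", x$scale))
  cat(sprintf("  backgrounds: b_x = %.5g, b_y = %.5g\n",
              x$background_x, x$background_y))
  if (is.finite(x$residual_sd))
    cat(sprintf("  residual SD %.4g over n = %d pairs\n", x$residual_sd, x$n))
  invisible(x)
}

#' Subtract a fluorescence background with a positive floor
#'
#' Background-corrected values are clamped from below at `floor` so that
#' log-log interpolation and plotting remain defined; clamping (rather than
#' erroring) is the contract for readings at or below background.
#'
#' @param values Fluorescence readings.
#' @param background Additive channel background.
#' @param floor Positive lower clamp (default `1e-6 * max(values)`).
#' @return Corrected values, all > 0.
#' @export
subtract_background <- function(values, background,
                                floor = 1e-6 * max(values)) {
  if (!is.finite(floor) || floor <= 0) stop("floor must be > 0", call. = FALSE)
  pmax(values - background, floor)
}
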
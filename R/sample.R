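#' Paired predictor/outcome observations for one necessity analysis
#'
#' Bundles the paired scores of one predictor-outcome analysis together with
#' optional declared (theoretical) scale ranges. All downstream estimators
#' (`[nca_analyze()]`, `[nca_permutation_test()]`, bottleneck functions)
#' consume this container. Missing values must be resolved before
#' construction; use pairwise-complete extraction upstream.
#'
#' @param x,y Numeric vectors of equal length: predictor scores and outcome
#'   scores. Both must be finite; at least 3 pairs are required.
#' @param label Optional free-text label (e.g. `"RSES -> Drive for Thinness"`).
#' @param x_range,y_range Optional length-2 numeric vectors `(min, max)`
#'   declaring the theoretical scale range. When given, every observation
#'   must lie inside them; they enable `scope_mode = "theoretical"`.
#'
#' @return An object of class `bivariate_sample`: a list with elements
#'   `x`, `y`, `n`, `label`, `x_range`, `y_range`.
#' @examples
#' s <- bivariate_sample(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
#' s$n
#' @export
bivariate_sample <- function(x, y, label = NULL,
                             x_range = NULL, y_range = NULL) {
  if (!is.numeric(x) || !is.numeric(y))
    abort_validation("`x` and `y` must be numeric vectors")
  if (length(x) != length(y))
    abort_validation(sprintf("`x` (n = %d) and `y` (n = %d) differ in length",
                             length(x), length(y)))
  if (anyNA(x) || anyNA(y) || !all(is.finite(x)) || !all(is.finite(y)))
    abort_validation("all observations must be finite; resolve missing values upstream")
  if (length(x) < 3L)
    abort_validation("a bivariate sample needs at least 3 observations")
  check_range <- function(v, rng, axis) {
    if (is.null(rng)) return(NULL)
    if (!is.numeric(rng) || length(rng) != 2L || rng[1] >= rng[2])
      abort_validation(sprintf("declared %s_range must be (min, max) with min < max", axis))
    bad <- which(v < rng[1] | v > rng[2])
    if (length(bad))
      abort_validation(sprintf(
        "%d %s value(s) outside declared range [%g, %g] (first at position %d)",
        length(bad), axis, rng[1], rng[2], bad[1]))
    as.numeric(rng)
  }
  x_range <- check_range(x, x_range, "x")
  y_range <- check_range(y, y_range, "y")
  structure(list(x = as.numeric(x), y = as.numeric(y), n = length(x),
                 label = label, x_range = x_range, y_range = y_range),
            class = "bivariate_sample")
}

#' @export
print.bivariate_sample <- function(x, ...) {
  cat("Bivariate sample", if (!is.null(x$label)) paste0("'", x$label, "'"),
      sprintf("(n = %d)\n", x$n))
  cat(sprintf("  x: [%g, %g]%s\n", min(x$x), max(x$x),
              if (!is.null(x$x_range))
                sprintf(" declared [%g, %g]", x$x_range[1], x$x_range[2])
              else ""))
  cat(sprintf("  y: [%g, %g]%s\n", min(x$y), max(x$y),
              if (!is.null(x$y_range))
                sprintf(" declared [%g, %g]", x$y_range[1], x$y_range[2])
              else ""))
  invisible(x)
}

as_bivariate_sample <- function(sample) {
  if (!inherits(sample, "bivariate_sample"))
    abort_validation("expected a `bivariate_sample` object")
  sample
}
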
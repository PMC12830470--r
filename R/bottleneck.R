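#' Predictor level required for an outcome level
#'
#' Necessity in degree: given a CE-FDH ceiling, finds the predictor level
#' that must be reached (upper-left corner, direction `"at_least"`) or not
#' exceeded (upper-right corner, direction `"at_most"`) for the outcome
#' level `y_level` to be attainable. When the outcome level is attainable
#' at every predictor value in the scope, the result is flagged `nn`
#' ("not necessary") and the reported level is the scope boundary on the
#' non-binding side.
#'
#' With a theoretical scope, outcome levels above the highest observed
#' ceiling value are attainable at no predictor value; these return
#' `attainable = FALSE` with `x_required = NA`.
#'
#' @param ceiling An `nca_ceiling` from [cefdh_ceiling()].
#' @param y_level Outcome level inside the scope's y range.
#' @return An object of class `nca_required_level`: list with `y_level`,
#'   `x_required`, `direction`, `nn`, `attainable`.
#' @examples
#' s <- bivariate_sample(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
#' required_level(cefdh_ceiling(s, "upper_left"), 4)$x_required  # 4
#' @export
required_level <- function(ceiling, y_level) {
  stopifnot(inherits(ceiling, "nca_ceiling"))
  sc <- ceiling$scope
  check_number(y_level, "y_level")
  if (y_level < sc$y_min || y_level > sc$y_max)
    abort_validation(sprintf("y_level %g outside scope y range [%g, %g]",
                             y_level, sc$y_min, sc$y_max))
  direction <- if (ceiling$corner == "upper_left") "at_least" else "at_most"
  ky <- ceiling$knots_y
  if (ky[1] >= y_level) {
    # ceiling already admits the level at the scope edge: holds everywhere
    x_req <- if (ceiling$corner == "upper_left") sc$x_min else sc$x_max
    return(structure(list(y_level = y_level, x_required = x_req,
                          direction = direction, nn = TRUE,
                          attainable = TRUE),
                     class = "nca_required_level"))
  }
  k <- match(TRUE, ky >= y_level)
  if (is.na(k))
    return(structure(list(y_level = y_level, x_required = NA_real_,
                          direction = direction, nn = FALSE,
                          attainable = FALSE),
                     class = "nca_required_level"))
  x_req <- ceiling$knots_x[k]
  if (ceiling$corner == "upper_right")
    x_req <- reflect_x(x_req, sc$x_min, sc$x_max)
  structure(list(y_level = y_level, x_required = x_req,
                 direction = direction, nn = FALSE, attainable = TRUE),
            class = "nca_required_level")
}

#' @export
print.nca_required_level <- function(x, ...) {
  if (!x$attainable) {
    cat(sprintf("y = %g is not attainable under the estimated ceiling\n",
                x$y_level))
  } else {
    cat(sprintf("y >= %g requires x %s %g%s\n", x$y_level,
                if (x$direction == "at_least") ">=" else "<=", x$x_required,
                if (x$nn) " (NN: attainable at any x in the scope)" else ""))
  }
  invisible(x)
}

#' Bottleneck table
#'
#' Tabulates, for a grid of outcome levels, the predictor level required to
#' make each level attainable. This is the necessity-in-degree companion of
#' the effect size: reading the table at a clinically meaningful outcome
#' level gives the predictor threshold that acts as its bottleneck.
#'
#' @param ceiling An `nca_ceiling`.
#' @param y_levels Strictly increasing outcome levels inside the scope
#'   (in `"actual"` units) or in `[0, 100]` (for `"percent_of_range"`).
#'   Default: the integer grid spanned by the scope's y range.
#' @param units `"actual"` (scale units, default) or `"percent_of_range"`
#'   (both columns expressed as percentages of their scope range).
#' @return A data frame of class `nca_bottleneck` with columns `y_level`,
#'   `x_required`, `direction`, `nn`, `attainable`; attributes `units` and
#'   `corner`.
#' @examples
#' s <- bivariate_sample(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
#' bottleneck_table(cefdh_ceiling(s, "upper_left"), 1:5)$x_required
#' @export
bottleneck_table <- function(ceiling, y_levels = NULL,
                             units = c("actual", "percent_of_range")) {
  stopifnot(inherits(ceiling, "nca_ceiling"))
  units <- match.arg(units)
  sc <- ceiling$scope
  if (is.null(y_levels)) {
    y_levels <- if (units == "actual")
      seq(base::ceiling(sc$y_min), floor(sc$y_max)) else seq(0, 100, by = 10)
  }
  if (length(y_levels) < 1L || anyNA(y_levels) || !is.numeric(y_levels))
    abort_validation("`y_levels` must be a non-empty numeric vector")
  if (is.unsorted(y_levels, strictly = TRUE))
    abort_validation("`y_levels` must be strictly increasing")
  actual <- if (units == "percent_of_range") {
    if (any(y_levels < 0 | y_levels > 100))
      abort_validation("percent_of_range levels must lie in [0, 100]")
    sc$y_min + y_levels / 100 * (sc$y_max - sc$y_min)
  } else y_levels
  rows <- lapply(actual, function(yl) required_level(ceiling, yl))
  x_req <- vapply(rows, function(r) r$x_required, numeric(1))
  if (units == "percent_of_range")
    x_req <- 100 * (x_req - sc$x_min) / (sc$x_max - sc$x_min)
  out <- data.frame(
    y_level = y_levels,
    x_required = x_req,
    direction = vapply(rows, function(r) r$direction, character(1)),
    nn = vapply(rows, function(r) r$nn, logical(1)),
    attainable = vapply(rows, function(r) r$attainable, logical(1)))
  fin <- out$x_required[out$attainable]
  mono_ok <- if (ceiling$corner == "upper_left")
    !is.unsorted(fin) else !is.unsorted(rev(fin))
  if (!mono_ok)
    abort_internal("bottleneck monotonicity violated; ceiling is inconsistent")
  structure(out, units = units, corner = ceiling$corner,
            class = c("nca_bottleneck", "data.frame"))
}

#' Prevalence / immunity partition at a bottleneck threshold
#'
#' Splits a sample by whether each case satisfies the necessary condition
#' (predictor at or below the threshold for the upper-right corner, at or
#' above it for the upper-left corner). Cases that do not meet the
#' condition cannot, under the estimated ceiling, reach the outcome
#' threshold: they are the "virtually immune" fraction. Among cases that
#' meet the condition, the fraction actually reaching the outcome threshold
#' (inclusive, `y >= y_threshold`) shows that the condition is necessary
#' but not sufficient.
#'
#' @param sample A [bivariate_sample()].
#' @param x_threshold Predictor threshold (typically a bottleneck level
#'   from [required_level()]).
#' @param y_threshold Outcome threshold (e.g. a subclinical cut-off).
#' @param corner `"upper_left"` or `"upper_right"`.
#' @return An object of class `nca_prevalence`: list with
#'   `met_condition_fraction`, `outcome_fraction_among_met`,
#'   `immune_fraction`, and the underlying counts `n`, `n_met`,
#'   `n_met_outcome`.
#' @export
prevalence_partition <- function(sample, x_threshold, y_threshold,
                                 corner = c("upper_left", "upper_right")) {
  sample <- as_bivariate_sample(sample)
  corner <- match_corner(corner)
  xr <- if (!is.null(sample$x_range)) sample$x_range else range(sample$x)
  yr <- if (!is.null(sample$y_range)) sample$y_range else range(sample$y)
  check_number(x_threshold, "x_threshold", lower = xr[1], upper = xr[2])
  check_number(y_threshold, "y_threshold", lower = yr[1], upper = yr[2])
  met <- if (corner == "upper_right")
    sample$x <= x_threshold else sample$x >= x_threshold
  n_met <- sum(met)
  n_met_outcome <- sum(sample$y[met] >= y_threshold)
  structure(list(
    met_condition_fraction = n_met / sample$n,
    outcome_fraction_among_met = if (n_met > 0) n_met_outcome / n_met
                                 else NA_real_,
    immune_fraction = 1 - n_met / sample$n,
    n = sample$n, n_met = n_met, n_met_outcome = n_met_outcome),
    class = "nca_prevalence")
}

#' @export
print.nca_prevalence <- function(x, ...) {
  cat(sprintf("Met necessary condition: %.2f%% (%d/%d)\n",
              100 * x$met_condition_fraction, x$n_met, x$n))
  if (x$n_met > 0)
    cat(sprintf("  of whom reached the outcome threshold: %.2f%% (%d/%d)\n",
                100 * x$outcome_fraction_among_met, x$n_met_outcome, x$n_met))
  cat(sprintf("Virtually immune: %.2f%%\n", 100 * x$immune_fraction))
  invisible(x)
}
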
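#' Scope of a bivariate sample
#'
#' The scope is the rectangle of possible observations whose area is the
#' denominator of the necessity effect size d. In `"empirical"` mode it is
#' spanned by the observed minima and maxima; in `"theoretical"` mode by the
#' declared scale ranges of the sample.
#'
#' @param sample A [bivariate_sample()].
#' @param mode `"empirical"` (default) or `"theoretical"`. Theoretical mode
#'   requires declared `x_range`/`y_range` on the sample.
#' @return An object of class `nca_scope`: list with `x_min`, `x_max`,
#'   `y_min`, `y_max`, `area`, `mode`.
#' @examples
#' s <- bivariate_sample(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
#' nca_scope(s)$area  # 16
#' @export
nca_scope <- function(sample, mode = c("empirical", "theoretical")) {
  sample <- as_bivariate_sample(sample)
  mode <- match_scope_mode(mode)
  if (mode == "empirical") {
    xr <- range(sample$x); yr <- range(sample$y)
  } else {
    if (is.null(sample$x_range) || is.null(sample$y_range))
      abort_validation("theoretical scope requires declared x_range and y_range")
    xr <- sample$x_range; yr <- sample$y_range
  }
  if (xr[1] >= xr[2])
    abort_validation(sprintf("zero-scope: x range is flat at %g", xr[1]),
                     class = "ncafdh_zero_scope")
  if (yr[1] >= yr[2])
    abort_validation(sprintf("zero-scope: y range is flat at %g", yr[1]),
                     class = "ncafdh_zero_scope")
  structure(list(x_min = xr[1], x_max = xr[2], y_min = yr[1], y_max = yr[2],
                 area = diff(xr) * diff(yr), mode = mode),
            class = "nca_scope")
}

#' @export
print.nca_scope <- function(x, ...) {
  cat(sprintf("Scope (%s): x [%g, %g] x y [%g, %g], area %g\n",
              x$mode, x$x_min, x$x_max, x$y_min, x$y_max, x$area))
  invisible(x)
}

# Reflect x about the midline of [x_min, x_max]; involutive.
reflect_x <- function(x, x_min, x_max) x_min + x_max - x

#' Free-disposal-hull peers of a sample
#'
#' A peer is an observation on the upper envelope of the scatter: for the
#' upper-left corner, a point not dominated by any other point with
#' smaller-or-equal x and greater-or-equal y. The CE-FDH ceiling is the step
#' function through the peers. The upper-right corner is handled by
#' reflecting x, running the upper-left search, and mapping back.
#'
#' Duplicate x values are collapsed to the maximum y at that x before the
#' search, and exact duplicates are kept once: the hull depends only on the
#' upper envelope.
#'
#' @param sample A [bivariate_sample()].
#' @param corner `"upper_left"` or `"upper_right"`.
#' @return A data frame with columns `x`, `y` (original units), ordered by
#'   increasing `x`; every row is an observation of the sample.
#' @examples
#' s <- bivariate_sample(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
#' find_peers(s, "upper_left")  # (1,1), (2,3), (4,5)
#' @export
find_peers <- function(sample, corner = c("upper_left", "upper_right")) {
  sample <- as_bivariate_sample(sample)
  corner <- match_corner(corner)
  x <- sample$x
  if (corner == "upper_right") x <- reflect_x(x, min(x), max(x))
  env <- upper_envelope(x, sample$y)
  px <- env$x
  if (corner == "upper_right") {
    px <- reflect_x(px, min(sample$x), max(sample$x))
    o <- order(px)
    return(data.frame(x = px[o], y = env$y[o]))
  }
  data.frame(x = px, y = env$y)
}

# Upper-left-frame envelope: unique x positions where the running maximum of
# y (in x order) strictly increases. First (smallest-x) point always enters.
upper_envelope <- function(x, y) {
  o <- order(x, y)
  xs <- x[o]; ys <- y[o]
  n <- length(xs)
  last_of_x <- c(xs[-1] != xs[-n], TRUE)   # collapse duplicate x to max y
  xs <- xs[last_of_x]; ys <- cummax(ys)[last_of_x]
  keep <- c(TRUE, ys[-1] > ys[-length(ys)])  # strict increase => peer
  list(x = xs[keep], y = ys[keep])
}

#' CE-FDH ceiling line
#'
#' Builds the ceiling envelopment - free disposal hull: the non-decreasing
#' step function through the peers, below which every observation lies. The
#' step jumps at each peer's x (the peer's y is attained from that x
#' rightward); left of the first peer the ceiling takes the first peer's y.
#'
#' @inheritParams find_peers
#' @param scope An [nca_scope()] consistent with the sample, or `NULL` to
#'   compute one from `scope_mode`.
#' @param scope_mode Passed to [nca_scope()] when `scope` is `NULL`.
#' @return An object of class `nca_ceiling`: list with `peers` (data frame,
#'   original units), `corner`, `scope`, plus internal step-function knots.
#' @seealso [ceiling_value()], [ceiling_area()], [nca_analyze()]
#' @export
cefdh_ceiling <- function(sample, corner = c("upper_left", "upper_right"),
                          scope = NULL,
                          scope_mode = c("empirical", "theoretical")) {
  sample <- as_bivariate_sample(sample)
  corner <- match_corner(corner)
  if (is.null(scope)) scope <- nca_scope(sample, scope_mode)
  if (!inherits(scope, "nca_scope"))
    abort_validation("`scope` must be an nca_scope object")
  if (any(sample$x < scope$x_min | sample$x > scope$x_max) ||
      any(sample$y < scope$y_min | sample$y > scope$y_max))
    abort_validation("sample has observations outside the given scope")
  xul <- if (corner == "upper_right")
    reflect_x(sample$x, scope$x_min, scope$x_max) else sample$x
  env <- upper_envelope(xul, sample$y)
  peers_x <- if (corner == "upper_right")
    reflect_x(env$x, scope$x_min, scope$x_max) else env$x
  o <- order(peers_x)
  structure(list(peers = data.frame(x = peers_x[o], y = env$y[o]),
                 corner = corner, scope = scope,
                 knots_x = env$x, knots_y = env$y),
            class = "nca_ceiling")
}

#' Evaluate a CE-FDH ceiling at predictor values
#'
#' Returns c(x), the highest outcome value the ceiling admits at each `x`.
#' For the upper-right corner the evaluation reflects x internally, so
#' `y <= ceiling_value(ceiling, x)` holds for every observation in either
#' corner orientation.
#'
#' @param ceiling An `nca_ceiling`.
#' @param x Numeric vector of predictor values (original units).
#' @return Numeric vector of ceiling heights.
#' @export
ceiling_value <- function(ceiling, x) {
  stopifnot(inherits(ceiling, "nca_ceiling"))
  sc <- ceiling$scope
  xx <- if (ceiling$corner == "upper_right")
    reflect_x(x, sc$x_min, sc$x_max) else x
  idx <- findInterval(xx, ceiling$knots_x)
  ceiling$knots_y[pmax(idx, 1L)]
}

#' @export
print.nca_ceiling <- function(x, ...) {
  cat(sprintf("CE-FDH ceiling (%s corner, %s scope): %d peer(s)\n",
              sub("_", "-", x$corner), x$scope$mode, nrow(x$peers)))
  print(x$peers, row.names = FALSE)
  invisible(x)
}

#' Area of the ceiling (empty) zone
#'
#' Integrates the gap between the step-function ceiling and the top of the
#' scope over the scope's x extent: the area of the corner region that
#' contains no observations.
#'
#' @param ceiling An `nca_ceiling` from [cefdh_ceiling()].
#' @return Non-negative area in scale-unit squared, at most the scope area.
#' @examples
#' s <- bivariate_sample(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
#' ceiling_area(cefdh_ceiling(s, "upper_left"))  # 8
#' @export
ceiling_area <- function(ceiling) {
  stopifnot(inherits(ceiling, "nca_ceiling"))
  sc <- ceiling$scope
  step_gap_area(ceiling$knots_x, ceiling$knots_y,
                sc$x_min, sc$x_max, sc$y_max)
}

# Area above the step function with knots (kx, ky) in the upper-left frame,
# below y_top, over [x_lo, x_hi]. Left of the first knot the step takes the
# first knot's y.
step_gap_area <- function(kx, ky, x_lo, x_hi, y_top) {
  m <- length(kx)
  edges <- c(x_lo, kx[-1], x_hi)
  sum((y_top - ky) * pmax(diff(edges), 0))
}

#' Necessity effect size
#'
#' The effect size d is the ratio of the ceiling-zone area to the scope
#' area: the fraction of the possibility space that the necessity
#' constraint leaves empty.
#'
#' @param ceiling_area Non-negative area of the empty zone.
#' @param scope_area Positive scope area; must be >= `ceiling_area`.
#' @return d in `[0, 1]`.
#' @export
effect_size <- function(ceiling_area, scope_area) {
  check_number(scope_area, "scope_area")
  check_number(ceiling_area, "ceiling_area")
  if (scope_area <= 0)
    abort_validation("`scope_area` must be positive")
  tol <- 1e-9 * scope_area
  if (ceiling_area < -tol || ceiling_area > scope_area + tol)
    abort_internal(sprintf(
      "inconsistent areas: ceiling %g outside [0, scope %g]",
      ceiling_area, scope_area))
  min(max(ceiling_area / scope_area, 0), 1)
}

#' Benchmark label for a necessity effect size
#'
#' Maps d to the conventional NCA benchmarks: `0` none, `(0, 0.10)` small,
#' `[0.10, 0.30)` medium, `[0.30, 0.50)` large, `>= 0.50` very large.
#'
#' @param d Effect size in `[0, 1]`.
#' @return One of `"none"`, `"small"`, `"medium"`, `"large"`, `"very_large"`.
#' @examples
#' classify_effect(0.25)  # "medium"
#' @export
classify_effect <- function(d) {
  check_number(d, "d", lower = 0, upper = 1)
  if (d == 0) "none"
  else if (d < 0.10) "small"
  else if (d < 0.30) "medium"
  else if (d < 0.50) "large"
  else "very_large"
}

#' Full CE-FDH necessity analysis of one sample
#'
#' Composes scope construction, peer search, ceiling estimation, and effect
#' size computation into the core result record of an NCA: the estimate of
#' how necessary the predictor is for the outcome.
#'
#' @inheritParams cefdh_ceiling
#' @return An object of class `nca_estimate`: list with `d`, `ceiling_area`,
#'   `scope_area`, `accuracy` (fraction of observations on or below the
#'   ceiling; 1 by construction for CE-FDH), `corner`, `n_used`, `label`
#'   (benchmark classification), and the underlying `ceiling` and `scope`.
#' @examples
#' s <- bivariate_sample(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
#' est <- nca_analyze(s, "upper_left")
#' est$d       # 0.5
#' est$label   # "very_large"
#' @export
nca_analyze <- function(sample, corner = c("upper_left", "upper_right"),
                        scope_mode = c("empirical", "theoretical")) {
  sample <- as_bivariate_sample(sample)
  corner <- match_corner(corner)
  scope_mode <- match_scope_mode(scope_mode)
  scope <- nca_scope(sample, scope_mode)
  ceiling <- cefdh_ceiling(sample, corner, scope = scope)
  c_area <- ceiling_area(ceiling)
  d <- effect_size(c_area, scope$area)
  acc <- mean(sample$y <= ceiling_value(ceiling, sample$x) + 1e-9)
  structure(list(d = d, ceiling_area = c_area, scope_area = scope$area,
                 accuracy = acc, corner = corner, n_used = sample$n,
                 label = classify_effect(d), ceiling = ceiling,
                 scope = scope, sample_label = sample$label),
            class = "nca_estimate")
}

#' @export
print.nca_estimate <- function(x, ...) {
  cat("CE-FDH necessity analysis",
      if (!is.null(x$sample_label)) paste0("'", x$sample_label, "'"), "\n")
  cat(sprintf("  n = %d, corner = %s, scope = %s (area %.4g)\n",
              x$n_used, sub("_", "-", x$corner), x$scope$mode, x$scope_area))
  cat(sprintf("  ceiling zone = %.4g, d = %.3f (%s), accuracy = %.3f\n",
              x$ceiling_area, x$d, sub("_", " ", x$label), x$accuracy))
  invisible(x)
}

# Fast d for resampling loops: x, y in original units; reflection and
# empirical/theoretical scope handled inline. xlim/ylim are the scope
# bounds (NULL = empirical). Returns NA for a flat (zero-scope) sample.
cefdh_d_quick <- function(x, y, corner = "upper_left",
                          xlim = NULL, ylim = NULL) {
  if (corner == "upper_right") {
    x <- -x
    if (!is.null(xlim)) xlim <- c(-xlim[2], -xlim[1])
  }
  o <- order(x)
  xs <- x[o]; cy <- cummax(y[o])
  n <- length(xs)
  last <- c(xs[-1] != xs[-n], TRUE)
  u <- xs[last]; cu <- cy[last]
  m <- length(u)
  x_lo <- if (is.null(xlim)) u[1] else xlim[1]
  x_hi <- if (is.null(xlim)) u[m] else xlim[2]
  y_lo <- if (is.null(ylim)) min(y) else ylim[1]
  y_hi <- if (is.null(ylim)) cu[m] else ylim[2]
  sa <- (x_hi - x_lo) * (y_hi - y_lo)
  if (!is.finite(sa) || sa <= 0) return(NA_real_)
  edges <- c(x_lo, u[-1], x_hi)
  sum((y_hi - cu) * pmax(diff(edges), 0)) / sa
}
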
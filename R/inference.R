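#' Approximate permutation test for the necessity effect size
#'
#' Tests whether the observed CE-FDH effect size d could have arisen under
#' independence of predictor and outcome. Each resample randomly permutes
#' the x values against the fixed y values and recomputes d with the same
#' corner and scope mode, so the permutation null preserves both marginal
#' distributions. The p-value uses the add-one Monte-Carlo estimator
#' `(1 + #\{d* >= d_obs\}) / (resamples + 1)`, which can never return an
#' impossible p of exactly zero.
#'
#' @param sample A [bivariate_sample()].
#' @param corner `"upper_left"` or `"upper_right"`.
#' @param resamples Number of random permutations (>= 1); the conventional
#'   setting is 10000.
#' @param seed Integer seed; the test is fully deterministic given it.
#' @param scope_mode `"empirical"` or `"theoretical"` (see [nca_scope()]).
#' @return An object of class `nca_permutation`: list with `p_value`,
#'   `d_observed`, `resamples`, `null_d_summary` (`mean`, `sd`, `q95`),
#'   `seed`.
#' @export
nca_permutation_test <- function(sample,
                                 corner = c("upper_left", "upper_right"),
                                 resamples = 10000, seed,
                                 scope_mode = c("empirical", "theoretical")) {
  sample <- as_bivariate_sample(sample)
  corner <- match_corner(corner)
  scope_mode <- match_scope_mode(scope_mode)
  resamples <- check_number(resamples, "resamples", lower = 1,
                            integer = TRUE)
  seed <- check_seed(seed)
  scope <- nca_scope(sample, scope_mode)  # rejects zero-scope input
  xlim <- ylim <- NULL
  if (scope_mode == "theoretical") {
    xlim <- c(scope$x_min, scope$x_max)
    ylim <- c(scope$y_min, scope$y_max)
  }
  x <- sample$x; y <- sample$y
  d_obs <- cefdh_d_quick(x, y, corner, xlim, ylim)
  d_null <- with_seed(seed, vapply(seq_len(resamples), function(r) {
    cefdh_d_quick(x[sample.int(length(x))], y, corner, xlim, ylim)
  }, numeric(1)))
  p <- (1 + sum(d_null >= d_obs - 1e-12)) / (resamples + 1)
  structure(list(p_value = p, d_observed = d_obs,
                 resamples = as.integer(resamples),
                 null_d_summary = list(mean = mean(d_null), sd = sd(d_null),
                                       q95 = stats::quantile(d_null, 0.95,
                                                             names = FALSE)),
                 seed = seed),
            class = "nca_permutation")
}

#' @export
print.nca_permutation <- function(x, ...) {
  cat(sprintf("Approximate permutation test: d = %.3f, p = %.4g (%d resamples)\n",
              x$d_observed, x$p_value, x$resamples))
  cat(sprintf("  null d: mean %.3f, sd %.3f, q95 %.3f\n",
              x$null_d_summary$mean, x$null_d_summary$sd,
              x$null_d_summary$q95))
  invisible(x)
}

#' Necessity-in-kind decision rule
#'
#' A predictor is declared a necessary condition in kind only when the
#' effect size is at least `d_min` (default 0.10, the lower bound of the
#' medium benchmark) and the permutation p-value is below `alpha`.
#'
#' @param d Effect size(s) in `[0, 1]`.
#' @param p Permutation p-value(s) in `(0, 1]`.
#' @param d_min Minimum effect size; default 0.10.
#' @param alpha Significance level; default 0.05.
#' @return Logical (vectorized over `d` and `p`).
#' @examples
#' necessity_in_kind(0.25, 0.003)  # TRUE
#' necessity_in_kind(0.20, 0.415)  # FALSE
#' @export
necessity_in_kind <- function(d, p, d_min = 0.10, alpha = 0.05) {
  if (!is.numeric(d) || !is.numeric(p) || any(d < 0 | d > 1, na.rm = TRUE))
    abort_validation("`d` must lie in [0, 1] and `p` in (0, 1]")
  if (any(p <= 0 | p > 1, na.rm = TRUE))
    abort_validation("`p` must lie in (0, 1]")
  check_number(d_min, "d_min", lower = 0, upper = 1)
  check_number(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  d >= d_min & p < alpha
}

#' Simulate a dataset with a planted necessity ceiling
#'
#' Draws points uniformly on the unit square with a corner region of
#' relative area `true_d` left empty. The empty region sits above a
#' slope-one (after corner orientation) straight boundary, i.e. for
#' `true_d <= 0.5` a right triangle with equal legs `sqrt(2 * true_d)` in
#' the chosen corner; rejection sampling guarantees that no generated point
#' falls inside it. This is the data-generating process used by
#' [estimate_power()] and [minimum_sample_size()].
#'
#' @param n Number of points (>= 3).
#' @param true_d Relative empty-zone area in `[0, 1)`.
#' @param corner `"upper_left"` or `"upper_right"`.
#' @param seed Integer seed; output is deterministic given it.
#' @return A [bivariate_sample()] with declared ranges `(0, 1)` on both
#'   axes.
#' @export
simulate_necessity_dataset <- function(n, true_d,
                                       corner = c("upper_left", "upper_right"),
                                       seed) {
  n <- check_number(n, "n", lower = 3, integer = TRUE)
  check_number(true_d, "true_d", lower = 0)
  if (true_d >= 1)
    abort_validation("`true_d` must be < 1: the empty zone cannot fill the scope")
  corner <- match_corner(corner)
  seed <- check_seed(seed)
  h <- planted_boundary(true_d)
  with_seed(seed, {
    u <- stats::runif(n)
    v <- stats::runif(n)
    repeat {
      bad <- v > h(if (corner == "upper_left") u else 1 - u)
      if (!any(bad)) break
      u[bad] <- stats::runif(sum(bad))
      v[bad] <- stats::runif(sum(bad))
    }
    bivariate_sample(u, v, label = sprintf("planted d = %g", true_d),
                     x_range = c(0, 1), y_range = c(0, 1))
  })
}

# Boundary height of the planted empty zone on the unit square, in the
# upper-left frame: the zone is {v > h(u)} with h(u) = clip(u + t, 0, 1)
# and the offset t chosen so its area equals d. Slope-one hypotenuse;
# for d > 1/2 the boundary hits the floor and the kept region is the
# lower-right triangle of area 1 - d.
planted_boundary <- function(d) {
  t <- if (d <= 0.5) 1 - sqrt(2 * d) else sqrt(2 * (1 - d)) - 1
  function(u) pmin(pmax(u + t, 0), 1)
}

#' Specification for simulation-based power analysis
#'
#' Fixes the operating conditions under which [estimate_power()] and
#' [minimum_sample_size()] simulate the necessity test: the planted effect
#' size, the decision rule (`d_min`, `alpha`), the Monte-Carlo effort, and
#' the master seed.
#'
#' @param true_d Planted effect size in `(0, 1)`.
#' @param alpha Significance level in `(0, 1)`; default 0.05.
#' @param target_power Desired power in `(0, 1)`; default 0.80.
#' @param resamples_per_test Permutation resamples per simulated test.
#' @param simulations Simulated datasets per sample size.
#' @param seed Master seed; per-simulation seeds are derived from it and
#'   reused across sample sizes (common random numbers).
#' @param d_min Minimum effect size of the decision rule; default 0.10.
#' @param corner Corner of the planted zone.
#' @return An object of class `nca_power_spec`.
#' @export
power_spec <- function(true_d, alpha = 0.05, target_power = 0.80,
                       resamples_per_test = 200, simulations = 500,
                       seed = 1, d_min = 0.10,
                       corner = c("upper_left", "upper_right")) {
  check_number(true_d, "true_d", lower = 0, upper = 1, strict = TRUE)
  check_number(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  check_number(target_power, "target_power", lower = 0, upper = 1,
               strict = TRUE)
  check_number(resamples_per_test, "resamples_per_test", lower = 1,
               integer = TRUE)
  check_number(simulations, "simulations", lower = 1, integer = TRUE)
  check_number(d_min, "d_min", lower = 0, upper = 1)
  structure(list(true_d = true_d, alpha = alpha,
                 target_power = target_power,
                 resamples_per_test = as.integer(resamples_per_test),
                 simulations = as.integer(simulations),
                 seed = check_seed(seed), d_min = d_min,
                 corner = match_corner(corner)),
            class = "nca_power_spec")
}

#' Estimate the power of the necessity test at one sample size
#'
#' Simulates `spec$simulations` datasets from the planted-ceiling process
#' ([simulate_necessity_dataset()]) at `spec$true_d`, runs the CE-FDH
#' analysis plus permutation test on each, and returns the fraction for
#' which the necessity-in-kind rule fires.
#'
#' @param n Sample size (>= 5).
#' @param spec A [power_spec()].
#' @return Estimated power in `[0, 1]`.
#' @export
estimate_power <- function(n, spec) {
  n <- check_number(n, "n", lower = 5, integer = TRUE)
  stopifnot(inherits(spec, "nca_power_spec"))
  sim_seeds <- derive_seeds(spec$seed, spec$simulations)
  hits <- vapply(seq_len(spec$simulations), function(i) {
    ss <- derive_seeds(sim_seeds[i], 2)
    smp <- simulate_necessity_dataset(n, spec$true_d, spec$corner, ss[1])
    pt <- nca_permutation_test(smp, spec$corner, spec$resamples_per_test,
                               seed = ss[2])
    necessity_in_kind(pt$d_observed, pt$p_value, spec$d_min, spec$alpha)
  }, logical(1))
  mean(hits)
}

#' Minimum sample size reaching a target power
#'
#' Evaluates [estimate_power()] over a grid of sample sizes (with common
#' random numbers across grid points) and reports the smallest n whose
#' estimated power reaches `spec$target_power`.
#'
#' @param spec A [power_spec()].
#' @param n_min,n_max Grid bounds, `n_min < n_max`.
#' @param n_step Grid step.
#' @return An object of class `nca_power`: list with `n_grid`,
#'   `power_at_n`, `minimum_n` (`NA` when the target is not reached on the
#'   grid), `reached`, and the `spec`.
#' @export
minimum_sample_size <- function(spec, n_min = 40, n_max = 120, n_step = 5) {
  stopifnot(inherits(spec, "nca_power_spec"))
  n_min <- check_number(n_min, "n_min", lower = 5, integer = TRUE)
  n_max <- check_number(n_max, "n_max", integer = TRUE)
  n_step <- check_number(n_step, "n_step", lower = 1, integer = TRUE)
  if (n_min >= n_max) abort_validation("`n_min` must be smaller than `n_max`")
  n_grid <- seq(n_min, n_max, by = n_step)
  power_at_n <- vapply(n_grid, estimate_power, numeric(1), spec = spec)
  hit <- match(TRUE, power_at_n >= spec$target_power)
  structure(list(n_grid = as.integer(n_grid), power_at_n = power_at_n,
                 minimum_n = if (is.na(hit)) NA_integer_
                             else as.integer(n_grid[hit]),
                 reached = !is.na(hit), spec = spec),
            class = "nca_power")
}

#' @export
print.nca_power <- function(x, ...) {
  cat(sprintf("Power grid for planted d = %g (alpha %g, %d sims/n, %d resamples):\n",
              x$spec$true_d, x$spec$alpha, x$spec$simulations,
              x$spec$resamples_per_test))
  print(data.frame(n = x$n_grid, power = round(x$power_at_n, 3)),
        row.names = FALSE)
  if (x$reached)
    cat(sprintf("Minimum n for power >= %g: %d\n", x$spec$target_power,
                x$minimum_n))
  else
    cat(sprintf("Target power %g not reached on the grid\n",
                x$spec$target_power))
  invisible(x)
}
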
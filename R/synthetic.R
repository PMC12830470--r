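#' Specification of one bounded integer sum-score variable
#'
#' Describes a questionnaire sum-score to be emulated: its theoretical
#' range, the target mean and standard deviation of the generated scores,
#' and the MCAR missingness rate applied afterwards.
#'
#' @param name Column name in the generated table.
#' @param range Length-2 integer vector `(min, max)` of the theoretical
#'   scale range.
#' @param mean,sd Target moments of the generated (complete) scores.
#' @param missing_rate MCAR missingness probability in `[0, 1)`.
#' @return An object of class `variable_spec`.
#' @examples
#' variable_spec("rses_t0", c(10, 40), mean = 28.23, sd = 4.84,
#'               missing_rate = 0.07)
#' @export
variable_spec <- function(name, range, mean, sd, missing_rate = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    abort_validation("`name` must be a non-empty string")
  if (!is.numeric(range) || length(range) != 2L || range[1] >= range[2] ||
      any(range != round(range)))
    abort_validation("`range` must be an integer (min, max) with min < max")
  check_number(mean, "mean", lower = range[1], upper = range[2])
  check_number(sd, "sd", lower = 0, strict = TRUE)
  check_number(missing_rate, "missing_rate", lower = 0, upper = 1)
  if (missing_rate >= 1)
    abort_validation("`missing_rate` must be < 1")
  structure(list(name = name, range = as.integer(range), mean = mean,
                 sd = sd, missing_rate = missing_rate),
            class = "variable_spec")
}

#' Default variable specifications of the emulated self-esteem study
#'
#' One predictor (Rosenberg Self-Esteem Scale sum at baseline, range 10-40)
#' and three EDI-2 outcome subscales at 12-month follow-up: Drive for
#' Thinness (0-21), Body Dissatisfaction (0-25), Bulimia (0-21). Target
#' moments and MCAR missingness rates match the descriptive statistics the
#' generator is calibrated to emulate (RSES mean 28.23, sd 4.84, 7%
#' missing; outcomes 6.35/6.39 at 5%, 8.95/6.23 at 4%, 1.24/2.14 at 2%).
#'
#' @return Named list with elements `predictor` (a [variable_spec()]) and
#'   `outcomes` (list of three [variable_spec()]s).
#' @export
study_variable_specs <- function() {
  list(
    predictor = variable_spec("rses_t0", c(10, 40), 28.23, 4.84,
                              missing_rate = 0.07),
    outcomes = list(
      variable_spec("edi_dt_t12", c(0, 21), 6.35, 6.39,
                    missing_rate = 0.05),
      variable_spec("edi_bd_t12", c(0, 25), 8.95, 6.23,
                    missing_rate = 0.04),
      variable_spec("edi_bul_t12", c(0, 21), 1.24, 2.14,
                    missing_rate = 0.02)))
}

# Probabilities of a discretized normal on the integer grid `vals`,
# truncated to the grid by renormalization.
grid_probs <- function(mu, sigma, vals) {
  p <- stats::pnorm(vals + 0.5, mu, sigma) - stats::pnorm(vals - 0.5, mu, sigma)
  s <- sum(p)
  if (s <= 0) return(rep(1 / length(vals), length(vals)))
  p / s
}

grid_moments <- function(p, vals) {
  m <- sum(p * vals)
  list(mean = m, sd = sqrt(max(sum(p * (vals - m)^2), 0)))
}

# Fit (mu, sigma) of the discretized truncated normal to the spec's target
# moments. The mean is matched tightly; the sd is matched as closely as
# the bounded family allows (strong floor effects make some printed SDs
# unreachable within it). Errors when the targets are infeasible on the
# grid or the best fit is still far off.
calibrate_marginal <- function(spec) {
  key <- paste(spec$range[1], spec$range[2], spec$mean, spec$sd, sep = "|")
  hit <- .calibration_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- calibrate_marginal_impl(spec)
  assign(key, res, envir = .calibration_cache)
  res
}

.calibration_cache <- new.env(parent = emptyenv())

calibrate_marginal_impl <- function(spec) {
  vals <- spec$range[1]:spec$range[2]
  sd_cap <- sqrt((spec$mean - spec$range[1]) * (spec$range[2] - spec$mean))
  if (spec$sd >= sd_cap)
    abort_validation(sprintf(
      "infeasible moments for '%s': sd %g exceeds the bound %.3g implied by mean %g on [%d, %d]",
      spec$name, spec$sd, sd_cap, spec$mean, spec$range[1], spec$range[2]))
  obj <- function(par) {
    mom <- grid_moments(grid_probs(par[1], exp(par[2]), vals), vals)
    25 * (mom$mean - spec$mean)^2 + (mom$sd - spec$sd)^2
  }
  span <- diff(range(vals))
  starts <- list(c(spec$mean, log(spec$sd)),
                 c(spec$mean - 2 * spec$sd, log(2 * spec$sd)),
                 c(spec$mean - 6 * spec$sd, log(4 * spec$sd)),
                 c(mean(range(vals)), log(span / 4)))
  fit <- NULL
  for (st in starts) {
    f <- stats::optim(st, obj, control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(fit) || f$value < fit$value) fit <- f
  }
  p <- grid_probs(fit$par[1], exp(fit$par[2]), vals)
  mom <- grid_moments(p, vals)
  if (abs(mom$mean - spec$mean) > 0.25 ||
      abs(mom$sd - spec$sd) > max(0.25, 0.25 * spec$sd))
    abort_validation(sprintf(
      "calibration for '%s' failed: best achievable mean %.3f, sd %.3f vs targets %.3f, %.3f",
      spec$name, mom$mean, mom$sd, spec$mean, spec$sd))
  list(vals = vals, probs = p, mean = mom$mean, sd = mom$sd,
       mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Generate one predictor/outcome pair with a planted necessity ceiling
#'
#' Draws integer predictor scores from a discretized range-truncated normal
#' calibrated to the spec's target moments, then draws each outcome score
#' from its own calibrated marginal truncated below the planted straight
#' ceiling line (a corner empty zone of relative area `true_d` on the
#' theoretical-range rectangle). Truncated sampling guarantees zero
#' ceiling violations by construction.
#'
#' @param n Number of pairs.
#' @param spec_x,spec_y [variable_spec()]s for predictor and outcome.
#' @param true_d Relative empty-zone area in `[0, 1)` on the theoretical
#'   scope.
#' @param corner Corner of the empty zone (default `"upper_right"`: low x
#'   necessary for high y).
#' @param seed Integer seed.
#' @return List with `x`, `y` (integer vectors), `sample` (a
#'   [bivariate_sample()] with declared theoretical ranges), and `truth`
#'   (list: `true_d`, `corner`, `x_range`, `y_range`) accepted by
#'   [planted_ceiling_value()].
#' @export
generate_pair <- function(n, spec_x, spec_y, true_d,
                          corner = c("upper_left", "upper_right"),
                          seed) {
  n <- check_number(n, "n", lower = 3, integer = TRUE)
  stopifnot(inherits(spec_x, "variable_spec"),
            inherits(spec_y, "variable_spec"))
  check_number(true_d, "true_d", lower = 0)
  if (true_d >= 1) abort_validation("`true_d` must be < 1")
  corner <- match_corner(corner)
  seed <- check_seed(seed)
  gx <- calibrate_marginal(spec_x)
  gy <- calibrate_marginal(spec_y)
  truth <- list(true_d = true_d, corner = corner,
                x_range = as.numeric(spec_x$range),
                y_range = as.numeric(spec_y$range))
  with_seed(seed, {
    x <- gx$vals[sample.int(length(gx$vals), n, replace = TRUE,
                            prob = gx$probs)]
    y <- draw_y_below_ceiling(x, gy, truth)
    list(x = x, y = y,
         sample = bivariate_sample(x, y,
                                   label = sprintf("%s -> %s", spec_x$name,
                                                   spec_y$name),
                                   x_range = spec_x$range,
                                   y_range = spec_y$range),
         truth = truth)
  })
}

# Draw y from the calibrated marginal `gy`, truncated at the planted
# ceiling evaluated at each x (uses the current RNG stream).
draw_y_below_ceiling <- function(x, gy, truth) {
  kmax <- planted_ceiling_value(truth, x)
  y <- integer(length(x))
  for (km in sort(unique(kmax))) {
    idx <- which(kmax == km)
    ncat <- km - truth$y_range[1] + 1L
    p <- gy$probs[seq_len(ncat)]
    y[idx] <- gy$vals[sample.int(ncat, length(idx), replace = TRUE,
                                 prob = p / sum(p))]
  }
  y
}

#' Highest admissible outcome score under a planted ceiling
#'
#' Evaluates the straight-line ceiling planted by [generate_pair()] /
#' [generate_study()] at predictor values `x`: the largest integer outcome
#' score a generated pair may carry at that x.
#'
#' @param truth A `truth` record as returned by [generate_pair()] (fields
#'   `true_d`, `corner`, `x_range`, `y_range`).
#' @param x Numeric vector of predictor values.
#' @return Integer vector of maximal admissible outcome scores.
#' @export
planted_ceiling_value <- function(truth, x) {
  h <- planted_boundary(truth$true_d)
  u <- (x - truth$x_range[1]) / diff(truth$x_range)
  hu <- h(if (truth$corner == "upper_left") u else 1 - u)
  as.integer(truth$y_range[1] + floor(hu * diff(truth$y_range) + 1e-9))
}

#' Configuration of a synthetic study table
#'
#' @param n Number of participants (>= 10); default 84, the emulated
#'   study's size.
#' @param predictor,outcomes [variable_spec()]s; defaults from
#'   [study_variable_specs()].
#' @param true_d Named vector mapping each outcome name to its planted
#'   effect size in `[0, 1)`. Defaults to the effect sizes the emulated
#'   study reported (0.25, 0.22, 0.20).
#' @param corner Corner of the planted zones; default `"upper_right"`
#'   (low self-esteem necessary for high symptom levels).
#' @param seed Master seed.
#' @return An object of class `nca_study_sim_config`.
#' @export
synthetic_study_config <- function(n = 84, predictor = NULL, outcomes = NULL,
                                   true_d = c(edi_dt_t12 = 0.25,
                                              edi_bd_t12 = 0.22,
                                              edi_bul_t12 = 0.20),
                                   corner = c("upper_right", "upper_left"),
                                   seed = 1) {
  defaults <- study_variable_specs()
  if (is.null(predictor)) predictor <- defaults$predictor
  if (is.null(outcomes)) outcomes <- defaults$outcomes
  n <- check_number(n, "n", lower = 10, integer = TRUE)
  stopifnot(inherits(predictor, "variable_spec"))
  out_names <- vapply(outcomes, function(s) {
    stopifnot(inherits(s, "variable_spec")); s$name
  }, character(1))
  if (!all(out_names %in% names(true_d)))
    abort_validation("every outcome needs a `true_d` entry by name")
  if (any(true_d < 0 | true_d >= 1))
    abort_validation("all `true_d` values must lie in [0, 1)")
  structure(list(n = n, predictor = predictor, outcomes = outcomes,
                 true_d = true_d[out_names],
                 corner = match.arg(corner), seed = check_seed(seed)),
            class = "nca_study_sim_config")
}

#' Generate a full synthetic study table
#'
#' One shared predictor column plus one column per outcome, each outcome
#' drawn below its own planted ceiling given the shared predictor scores,
#' followed by MCAR missingness masks at each variable's rate. The truth
#' record (complete table, planted ceilings, masks) is retained so that
#' recovery can be assessed.
#'
#' @param config A [synthetic_study_config()].
#' @return An object of class `nca_synthetic_study`: list with `table`
#'   (data frame `id` + score columns, `NA` = missing), `truth` (list:
#'   `complete` table, named `true_d`, per-outcome `ceilings`, named
#'   `missing` masks), and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "nca_study_sim_config"))
  n_out <- length(config$outcomes)
  seeds <- derive_seeds(config$seed, 1L + 2L * n_out + 1L)
  gx <- calibrate_marginal(config$predictor)
  x <- with_seed(seeds[1], gx$vals[sample.int(length(gx$vals), config$n,
                                              replace = TRUE,
                                              prob = gx$probs)])
  tab <- data.frame(id = seq_len(config$n))
  tab[[config$predictor$name]] <- x
  ceilings <- list()
  for (j in seq_len(n_out)) {
    spec_y <- config$outcomes[[j]]
    truth_j <- list(true_d = unname(config$true_d[[spec_y$name]]),
                    corner = config$corner,
                    x_range = as.numeric(config$predictor$range),
                    y_range = as.numeric(spec_y$range))
    gy <- calibrate_marginal(spec_y)
    tab[[spec_y$name]] <- with_seed(seeds[1 + j],
                                    draw_y_below_ceiling(x, gy, truth_j))
    ceilings[[spec_y$name]] <- truth_j
  }
  complete <- tab
  vars <- c(config$predictor$name,
            vapply(config$outcomes, `[[`, character(1), "name"))
  rates <- c(config$predictor$missing_rate,
             vapply(config$outcomes, `[[`, numeric(1), "missing_rate"))
  masks <- list()
  for (k in seq_along(vars)) {
    mask <- with_seed(seeds[1 + n_out + k],
                      stats::runif(config$n) < rates[k])
    tab[[vars[k]]][mask] <- NA
    masks[[vars[k]]] <- mask
  }
  structure(list(table = tab,
                 truth = list(complete = complete,
                              true_d = config$true_d,
                              ceilings = ceilings, missing = masks),
                 config = config),
            class = "nca_synthetic_study")
}

#' @export
print.nca_synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: n = %d, %d outcome(s), corner %s\n",
              x$config$n, length(x$config$outcomes),
              sub("_", "-", x$config$corner)))
  cat("Planted d:", paste(sprintf("%s = %g", names(x$truth$true_d),
                                  x$truth$true_d), collapse = ", "), "\n")
  cat("Missing cells:",
      paste(sprintf("%s = %d", names(x$truth$missing),
                    vapply(x$truth$missing, sum, integer(1))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic study to CSV (and its truth record to JSON)
#'
#' The CSV uses one row per participant and empty cells for missing
#' values, matching the input contract of [read_study_csv()].
#'
#' @param study An `nca_synthetic_study`.
#' @param csv_path Output CSV path.
#' @param truth_path Optional JSON path for the truth record.
#' @return Invisibly, `csv_path`.
#' @export
write_synthetic_study <- function(study, csv_path, truth_path = NULL) {
  stopifnot(inherits(study, "nca_synthetic_study"))
  utils::write.csv(study$table, csv_path, row.names = FALSE, na = "")
  if (!is.null(truth_path)) {
    truth <- study$truth
    truth$true_d <- as.list(truth$true_d)
    truth$missing <- lapply(truth$missing, which)
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
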
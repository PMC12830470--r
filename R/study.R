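#' Default theoretical score ranges of the study layout
#'
#' @return Named list of `(min, max)` ranges for the default columns:
#'   RSES baseline sum (10-40) and the three EDI-2 12-month subscale sums
#'   (Drive for Thinness 0-21, Body Dissatisfaction 0-25, Bulimia 0-21).
#' @export
default_study_ranges <- function() {
  list(rses_t0 = c(10, 40), edi_dt_t12 = c(0, 21),
       edi_bd_t12 = c(0, 25), edi_bul_t12 = c(0, 21))
}

#' Configuration of an end-to-end necessity study
#'
#' Collects everything [run_study()] needs: where the data live, which
#' columns play predictor and outcomes, the corner and scope convention,
#' Monte-Carlo effort, the decision rule, the subclinical outcome
#' thresholds at which bottleneck levels and prevalence fractions are
#' reported, and (optionally) the imputation sensitivity settings.
#'
#' @param input Path to the study CSV (may be `NULL` when a table is
#'   passed to [run_study()] directly).
#' @param predictor,outcomes Column names; defaults match the study
#'   layout (`rses_t0`; `edi_dt_t12`, `edi_bd_t12`, `edi_bul_t12`).
#' @param corner Scope corner of the hypothesized empty zone; default
#'   `"upper_right"` (low predictor necessary for high outcome).
#' @param scope_mode `"empirical"` (default) or `"theoretical"`.
#' @param resamples Permutation resamples per outcome; default 10000.
#' @param seed Master seed for all stochastic steps.
#' @param subclinical_thresholds Named integer vector: outcome column ->
#'   subclinical cut-off. Defaults: Drive for Thinness >= 19, Body
#'   Dissatisfaction >= 20, Bulimia >= 8 (95th-percentile norms).
#' @param d_min,alpha Necessity-in-kind decision rule; defaults 0.10, 0.05.
#' @param ranges Named list of theoretical ranges per column.
#' @param imputation `NULL` (skip the sensitivity analysis) or a list with
#'   elements `m`, `iterations`, `donors` for [sensitivity_nca()].
#' @return An object of class `nca_study_config`.
#' @export
study_config <- function(input = NULL, predictor = "rses_t0",
                         outcomes = c("edi_dt_t12", "edi_bd_t12",
                                      "edi_bul_t12"),
                         corner = c("upper_right", "upper_left"),
                         scope_mode = c("empirical", "theoretical"),
                         resamples = 10000, seed = 1,
                         subclinical_thresholds = c(edi_dt_t12 = 19,
                                                    edi_bd_t12 = 20,
                                                    edi_bul_t12 = 8),
                         d_min = 0.10, alpha = 0.05,
                         ranges = default_study_ranges(),
                         imputation = NULL) {
  corner <- match.arg(corner)
  scope_mode <- match_scope_mode(scope_mode)
  resamples <- check_number(resamples, "resamples", lower = 1,
                            integer = TRUE)
  check_number(d_min, "d_min", lower = 0, upper = 1)
  check_number(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  if (!all(outcomes %in% names(subclinical_thresholds)))
    abort_validation("every outcome needs a subclinical threshold by name")
  for (v in intersect(names(subclinical_thresholds), names(ranges))) {
    rng <- ranges[[v]]
    check_number(subclinical_thresholds[[v]],
                 sprintf("subclinical_thresholds[%s]", v),
                 lower = rng[1], upper = rng[2])
  }
  if (!is.null(imputation) &&
      !all(c("m", "iterations", "donors") %in% names(imputation)))
    abort_validation("`imputation` must list m, iterations, donors (or be NULL)")
  structure(list(input = input, predictor = predictor, outcomes = outcomes,
                 corner = corner, scope_mode = scope_mode,
                 resamples = as.integer(resamples),
                 seed = check_seed(seed),
                 subclinical_thresholds = subclinical_thresholds,
                 d_min = d_min, alpha = alpha, ranges = ranges,
                 imputation = imputation),
            class = "nca_study_config")
}

#' Read and validate a study CSV
#'
#' Parses a delimited study table with a header row. Empty cells become
#' missing values; any non-numeric cell or value outside its declared
#' theoretical range is rejected with the offending column and row.
#'
#' @param path CSV path.
#' @param columns Character vector of required columns (beyond whatever
#'   else the file holds).
#' @param ranges Optional named list of `(min, max)` declared ranges used
#'   for validation.
#' @return A data frame with numeric score columns (`NA` = missing).
#' @export
read_study_csv <- function(path, columns = NULL, ranges = NULL) {
  if (!file.exists(path))
    abort_validation(sprintf("input file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  missing_cols <- setdiff(columns, names(tab))
  if (length(missing_cols))
    abort_validation(sprintf("missing column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  for (v in union(columns, intersect(names(ranges), names(tab)))) {
    raw <- tab[[v]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      abort_validation(sprintf("non-numeric value '%s' in column '%s', row %d",
                               raw[bad[1]], v, bad[1]))
    rng <- ranges[[v]]
    if (!is.null(rng)) {
      out <- which(!is.na(num) & (num < rng[1] | num > rng[2]))
      if (length(out))
        abort_validation(sprintf(
          "value %g in column '%s', row %d outside declared range [%g, %g]",
          num[out[1]], v, out[1], rng[1], rng[2]))
    }
    tab[[v]] <- num
  }
  tab
}

#' Per-variable descriptive statistics
#'
#' Complete-case n, mean, sample standard deviation (n - 1 denominator)
#' and empirical range for each requested variable.
#'
#' @param table Data frame.
#' @param vars Variables to summarize; default: all numeric columns
#'   except `id`.
#' @return Data frame with columns `variable`, `n`, `mean`, `sd`, `min`,
#'   `max`.
#' @export
study_descriptives <- function(table, vars = NULL) {
  if (is.null(vars))
    vars <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                    "id")
  rows <- lapply(vars, function(v) {
    if (!v %in% names(table))
      abort_validation(sprintf("column '%s' not in table", v))
    x <- table[[v]][!is.na(table[[v]])]
    if (!length(x))
      abort_validation(sprintf("column '%s' has no observed values", v))
    data.frame(variable = v, n = length(x), mean = mean(x),
               sd = stats::sd(x), min = min(x), max = max(x))
  })
  do.call(rbind, rows)
}

#' Run the full necessity study workflow
#'
#' For each outcome: pairwise complete-case extraction, CE-FDH analysis,
#' approximate permutation test, necessity-in-kind flag, bottleneck table
#' over the outcome's integer grid, the required predictor level at the
#' subclinical threshold, and the prevalence/immunity partition at that
#' level. Optionally re-runs the analysis on multiply-imputed tables
#' ([sensitivity_nca()]). All sub-seeds derive from `config$seed`; apart
#' from the timestamp the report is fully reproducible.
#'
#' @param config An [study_config()].
#' @param table Optional pre-parsed data frame; when `NULL` the table is
#'   read from `config$input` via [read_study_csv()].
#' @return An object of class `nca_study_report`.
#' @export
run_study <- function(config, table = NULL) {
  stopifnot(inherits(config, "nca_study_config"))
  vars <- c(config$predictor, config$outcomes)
  if (is.null(table)) {
    if (is.null(config$input))
      abort_validation("no input: give `config$input` or a `table`")
    table <- read_study_csv(config$input, vars, config$ranges)
  } else {
    missing_cols <- setdiff(vars, names(table))
    if (length(missing_cols))
      abort_validation(sprintf("missing column(s): %s",
                               paste(missing_cols, collapse = ", ")))
  }
  desc <- study_descriptives(table, vars)
  seeds <- derive_seeds(config$seed, length(config$outcomes) + 1L)
  per_outcome <- list()
  for (k in seq_along(config$outcomes)) {
    out <- config$outcomes[k]
    per_outcome[[out]] <- tryCatch(
      analyze_one_outcome(table, config, out, seeds[k]),
      error = function(e) stop(errorCondition(
        sprintf("outcome '%s': %s", out, conditionMessage(e)),
        class = setdiff(class(e), c("error", "condition")))))
  }
  sensitivity <- NULL
  if (!is.null(config$imputation)) {
    imp <- config$imputation
    sensitivity <- sensitivity_nca(
      table, config$predictor, config$outcomes,
      corner = config$corner, scope_mode = config$scope_mode,
      resamples = config$resamples, seed = seeds[length(seeds)],
      m = imp$m, iterations = imp$iterations, donors = imp$donors,
      d_min = config$d_min, alpha = config$alpha, ranges = config$ranges)
  }
  structure(list(descriptives = desc, per_outcome = per_outcome,
                 sensitivity = sensitivity,
                 provenance = list(
                   config = config, outcome_seeds = seeds,
                   version = as.character(utils::packageVersion("ncafdh")),
                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "nca_study_report")
}

analyze_one_outcome <- function(table, config, out, seed) {
  x <- table[[config$predictor]]
  y <- table[[out]]
  cc <- !is.na(x) & !is.na(y)
  smp <- bivariate_sample(x[cc], y[cc],
                          label = sprintf("%s -> %s", config$predictor, out),
                          x_range = config$ranges[[config$predictor]],
                          y_range = config$ranges[[out]])
  est <- nca_analyze(smp, config$corner, config$scope_mode)
  perm <- nca_permutation_test(smp, config$corner, config$resamples,
                               seed = seed, scope_mode = config$scope_mode)
  flag <- necessity_in_kind(est$d, perm$p_value, config$d_min, config$alpha)
  bneck <- bottleneck_table(est$ceiling)
  y_thr <- config$subclinical_thresholds[[out]]
  sc <- est$scope
  if (y_thr >= sc$y_min && y_thr <= sc$y_max) {
    rl <- required_level(est$ceiling, y_thr)
    prevalence <- if (rl$attainable)
      prevalence_partition(smp, rl$x_required, y_thr, config$corner)
    else NULL
    threshold_note <- if (rl$attainable) NULL else
      "subclinical level unattainable under the estimated ceiling"
  } else {
    rl <- NULL
    prevalence <- NULL
    threshold_note <- sprintf(
      "subclinical threshold %g outside the %s scope y range [%g, %g]",
      y_thr, sc$mode, sc$y_min, sc$y_max)
  }
  peers <- est$ceiling$peers
  scatter <- data.frame(
    x = smp$x, y = smp$y,
    peer = paste(smp$x, smp$y) %in% paste(peers$x, peers$y),
    ceiling = ceiling_value(est$ceiling, smp$x))
  list(outcome = out, n = smp$n, estimate = est, permutation = perm,
       necessary = flag, bottleneck = bneck,
       subclinical_threshold = y_thr, required_at_threshold = rl,
       prevalence = prevalence, threshold_note = threshold_note,
       scatter = scatter, seed = seed)
}

#' @export
print.nca_study_report <- function(x, ...) {
  cfg <- x$provenance$config
  cat("Necessity study report\n")
  cat("======================\n")
  cat("Descriptives (complete cases per variable):\n")
  print(transform(x$descriptives, mean = round(mean, 2),
                  sd = round(sd, 2)), row.names = FALSE)
  for (out in names(x$per_outcome)) {
    r <- x$per_outcome[[out]]
    cat(sprintf("\n%s -> %s (n = %d):\n", cfg$predictor, out, r$n))
    cat(sprintf("  d = %.2f (%s), p = %.3f -> %snecessary in kind\n",
                r$estimate$d, sub("_", " ", r$estimate$label),
                r$permutation$p_value, if (r$necessary) "" else "not "))
    if (!is.null(r$required_at_threshold) &&
        r$required_at_threshold$attainable) {
      rl <- r$required_at_threshold
      cat(sprintf("  outcome >= %g requires %s %s %g%s\n",
                  r$subclinical_threshold, cfg$predictor,
                  if (rl$direction == "at_least") ">=" else "<=",
                  rl$x_required, if (rl$nn) " (NN)" else ""))
    }
    if (!is.null(r$prevalence))
      cat(sprintf("  met condition: %.2f%%; reached outcome among met: %.2f%%; immune: %.2f%%\n",
                  100 * r$prevalence$met_condition_fraction,
                  100 * r$prevalence$outcome_fraction_among_met,
                  100 * r$prevalence$immune_fraction))
    if (!is.null(r$threshold_note))
      cat("  note:", r$threshold_note, "\n")
  }
  if (!is.null(x$sensitivity)) { cat("\n"); print(x$sensitivity) }
  invisible(x)
}

# Plain nested list mirror of a report, suitable for JSON serialization
# and for equality checks across a write/read round trip.
as_report_list <- function(report) {
  stopifnot(inherits(report, "nca_study_report"))
  cfg <- report$provenance$config
  outcome_entry <- function(r) {
    est <- r$estimate
    rl <- r$required_at_threshold
    list(
      outcome = r$outcome, n = r$n,
      estimate = list(d = est$d, ceiling_area = est$ceiling_area,
                      scope_area = est$scope_area, accuracy = est$accuracy,
                      corner = est$corner, n_used = est$n_used,
                      label = est$label,
                      scope = est$scope[c("x_min", "x_max", "y_min",
                                          "y_max", "area", "mode")],
                      peers = est$ceiling$peers),
      permutation = list(p_value = r$permutation$p_value,
                         d_observed = r$permutation$d_observed,
                         resamples = r$permutation$resamples,
                         null_d_summary = r$permutation$null_d_summary,
                         seed = r$permutation$seed),
      necessary = r$necessary,
      bottleneck = as.data.frame(r$bottleneck),
      subclinical_threshold = r$subclinical_threshold,
      required_at_threshold = if (is.null(rl)) NULL else
        rl[c("y_level", "x_required", "direction", "nn", "attainable")],
      prevalence = if (is.null(r$prevalence)) NULL else
        r$prevalence[c("met_condition_fraction",
                       "outcome_fraction_among_met", "immune_fraction",
                       "n", "n_met", "n_met_outcome")],
      threshold_note = r$threshold_note,
      seed = r$seed)
  }
  sens <- report$sensitivity
  list(
    descriptives = report$descriptives,
    per_outcome = lapply(report$per_outcome, outcome_entry),
    sensitivity = if (is.null(sens)) NULL else
      list(m = sens$m, per_outcome = sens$per_outcome),
    provenance = list(
      predictor = cfg$predictor, outcomes = cfg$outcomes,
      corner = cfg$corner, scope_mode = cfg$scope_mode,
      resamples = cfg$resamples, seed = cfg$seed,
      d_min = cfg$d_min, alpha = cfg$alpha,
      subclinical_thresholds = as.list(cfg$subclinical_thresholds),
      outcome_seeds = report$provenance$outcome_seeds,
      version = report$provenance$version,
      timestamp = report$provenance$timestamp))
}

#' Write a study report to disk
#'
#' Writes the full report as JSON and, per outcome, the bottleneck table
#' and a scatter export (`x`, `y`, peer flag, ceiling value at x) as CSV
#' for external plotting of ceiling-line panels.
#'
#' @param report An `nca_study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("json", "csv")`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, formats = c("json", "csv")) {
  stopifnot(inherits(report, "nca_study_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(as_report_list(report), p, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null",
                         dataframe = "rows")
    paths <- c(paths, p)
  }
  if ("csv" %in% formats) {
    for (out in names(report$per_outcome)) {
      r <- report$per_outcome[[out]]
      bp <- file.path(dir, sprintf("bottleneck_%s.csv", out))
      bt <- as.data.frame(r$bottleneck)
      names(bt)[names(bt) == "nn"] <- "nn_flag"
      utils::write.csv(bt, bp, row.names = FALSE)
      sp <- file.path(dir, sprintf("scatter_%s.csv", out))
      utils::write.csv(r$scatter, sp, row.names = FALSE)
      paths <- c(paths, bp, sp)
    }
  }
  invisible(paths)
}
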
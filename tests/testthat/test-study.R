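write_temp_study <- function(n = 84, seed = 1, ...) {
  st <- generate_study(synthetic_study_config(n = n, seed = seed, ...))
  csv <- tempfile(fileext = ".csv")
  write_synthetic_study(st, csv)
  list(study = st, csv = csv)
}

test_that("read_study_csv parses, flags bad cells, and tolerates CRLF", {
  tmp <- write_temp_study(n = 40, seed = 2)
  rng <- default_study_ranges()
  tab <- read_study_csv(tmp$csv, names(rng), rng)
  expect_equal(nrow(tab), 40)
  expect_equal(sum(is.na(tab$rses_t0)),
               sum(is.na(tmp$study$table$rses_t0)))

  # out-of-range value rejected with its row number
  lines <- readLines(tmp$csv)
  bad <- sub("^([0-9]+),[0-9]*", "\\1,41", lines[4])
  bad_csv <- tempfile(fileext = ".csv")
  writeLines(c(lines[1:3], bad, lines[-(1:4)]), bad_csv)
  expect_error(read_study_csv(bad_csv, names(rng), rng),
               "row 3.*outside declared range|outside declared range",
               class = "ncafdh_validation_error")

  # non-numeric cell rejected by column and row
  bad2 <- sub("^([0-9]+),[0-9]*", "\\1,abc", lines[2])
  bad2_csv <- tempfile(fileext = ".csv")
  writeLines(c(lines[1], bad2, lines[-(1:2)]), bad2_csv)
  expect_error(read_study_csv(bad2_csv, names(rng), rng), "non-numeric",
               class = "ncafdh_validation_error")

  # CRLF endings parse identically
  crlf_csv <- tempfile(fileext = ".csv")
  writeLines(lines, crlf_csv, sep = "\r\n")
  expect_equal(read_study_csv(crlf_csv, names(rng), rng), tab)

  expect_error(read_study_csv(tmp$csv, c("nonexistent_col"), rng),
               "missing column", class = "ncafdh_validation_error")
  unlink(c(tmp$csv, bad_csv, bad2_csv, crlf_csv))
})

test_that("descriptives use complete cases and the n-1 sd", {
  tab <- data.frame(a = c(1, 2, 3), b = c(5, NA, 7))
  d <- study_descriptives(tab)
  expect_equal(d$mean[d$variable == "a"], 2)
  expect_equal(d$sd[d$variable == "a"], 1)
  expect_equal(d$min[d$variable == "a"], 1)
  expect_equal(d$max[d$variable == "a"], 3)
  expect_equal(d$n[d$variable == "b"], 2)
  expect_error(study_descriptives(data.frame(a = NA_real_)),
               "no observed values", class = "ncafdh_validation_error")
})

test_that("run_study assembles a coherent per-outcome report", {
  tmp <- write_temp_study(n = 84, seed = 33)
  cfg <- study_config(input = tmp$csv, resamples = 200, seed = 9)
  rep <- run_study(cfg)
  expect_s3_class(rep, "nca_study_report")
  expect_named(rep$per_outcome, c("edi_dt_t12", "edi_bd_t12", "edi_bul_t12"))
  tab <- read_study_csv(tmp$csv, NULL, default_study_ranges())
  for (out in names(rep$per_outcome)) {
    r <- rep$per_outcome[[out]]
    # per-outcome n equals the pairwise complete-case count
    expect_equal(r$n, sum(!is.na(tab$rses_t0) & !is.na(tab[[out]])))
    # the flag is a pure function of (d, p, d_min, alpha)
    expect_identical(r$necessary,
                     necessity_in_kind(r$estimate$d, r$permutation$p_value,
                                       cfg$d_min, cfg$alpha))
    # estimate and permutation describe the same observed d
    expect_identical(r$estimate$d, r$permutation$d_observed)
    # bottleneck rows cover the integer grid of the empirical scope
    sc <- r$estimate$scope
    expect_equal(nrow(r$bottleneck),
                 length(seq(ceiling(sc$y_min), floor(sc$y_max))))
    # scatter export peer flags match find_peers
    smp <- bivariate_sample(tab$rses_t0[!is.na(tab$rses_t0) &
                                          !is.na(tab[[out]])],
                            tab[[out]][!is.na(tab$rses_t0) &
                                         !is.na(tab[[out]])])
    peers <- find_peers(smp, "upper_right")
    expect_equal(sort(unique(paste(r$scatter$x[r$scatter$peer],
                                   r$scatter$y[r$scatter$peer]))),
                 sort(paste(peers$x, peers$y)))
  }
  unlink(tmp$csv)
})

test_that("reports are reproducible apart from the timestamp", {
  tmp <- write_temp_study(n = 60, seed = 41)
  cfg <- study_config(input = tmp$csv, resamples = 100, seed = 13)
  a <- ncafdh:::as_report_list(run_study(cfg))
  b <- ncafdh:::as_report_list(run_study(cfg))
  a$provenance$timestamp <- b$provenance$timestamp <- NULL
  expect_identical(a, b)
  unlink(tmp$csv)
})

test_that("degenerate resampling still yields a well-formed report", {
  tmp <- write_temp_study(n = 50, seed = 55)
  rep <- run_study(study_config(input = tmp$csv, resamples = 1, seed = 3))
  for (r in rep$per_outcome)
    expect_true(r$permutation$p_value %in% c(0.5, 1))
  unlink(tmp$csv)
})

test_that("the optional imputation stage attaches a sensitivity record at full n", {
  tmp <- write_temp_study(n = 84, seed = 61)
  cfg <- study_config(input = tmp$csv, resamples = 50, seed = 17,
                      imputation = list(m = 2, iterations = 2, donors = 5))
  rep <- run_study(cfg)
  expect_s3_class(rep$sensitivity, "nca_sensitivity")
  for (out in rep$sensitivity$per_outcome) expect_equal(out$n, 84)
  unlink(tmp$csv)
})

test_that("write_report round-trips through JSON and CSV", {
  tmp <- write_temp_study(n = 60, seed = 71)
  rep <- run_study(study_config(input = tmp$csv, resamples = 100, seed = 5))
  dir <- tempfile()
  paths <- write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  js <- jsonlite::read_json(file.path(dir, "report.json"),
                            simplifyVector = TRUE)
  for (out in names(rep$per_outcome)) {
    r <- rep$per_outcome[[out]]
    expect_equal(js$per_outcome[[out]]$estimate$d, r$estimate$d)
    expect_equal(js$per_outcome[[out]]$permutation$p_value,
                 r$permutation$p_value)
    expect_equal(js$per_outcome[[out]]$necessary, r$necessary)
    bt <- utils::read.csv(file.path(dir, sprintf("bottleneck_%s.csv", out)))
    expect_equal(nrow(bt), nrow(r$bottleneck))
    sc <- utils::read.csv(file.path(dir, sprintf("scatter_%s.csv", out)))
    expect_equal(sc$peer, r$scatter$peer)
    expect_equal(sc$ceiling, r$scatter$ceiling)
  }
  unlink(dir, recursive = TRUE)
  unlink(tmp$csv)
})
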
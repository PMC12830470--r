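test_that("empirical and theoretical scopes are computed from the right ranges", {
  s <- toy_sample()
  sc <- nca_scope(s)
  expect_equal(c(sc$x_min, sc$x_max, sc$y_min, sc$y_max), c(1, 5, 1, 5))
  expect_equal(sc$area, 16)

  # scale-typical ranges: predictor 15-38 observed, outcome 0-21 observed
  s2 <- bivariate_sample(c(15, 20, 38, 25), c(3, 0, 10, 21))
  expect_equal(nca_scope(s2)$area, 23 * 21)

  s3 <- bivariate_sample(c(15, 20, 38), c(3, 0, 10),
                         x_range = c(10, 40), y_range = c(0, 21))
  sct <- nca_scope(s3, "theoretical")
  expect_equal(sct$area, 30 * 21)
  expect_error(nca_scope(s2, "theoretical"), "declared")
})

test_that("degenerate samples raise a zero-scope error naming the flat axis", {
  sy <- bivariate_sample(c(1, 2, 3), c(4, 4, 4))
  expect_error(nca_scope(sy), "y range is flat", class = "ncafdh_zero_scope")
  sx <- bivariate_sample(c(2, 2, 2), c(1, 2, 3))
  expect_error(nca_scope(sx), "x range is flat", class = "ncafdh_zero_scope")
  expect_error(nca_analyze(sy), class = "ncafdh_zero_scope")
})

test_that("find_peers returns the non-dominated points, collapsed and ordered", {
  p <- find_peers(toy_sample(), "upper_left")
  expect_equal(p$x, c(1, 2, 4))
  expect_equal(p$y, c(1, 3, 5))

  # single maximal point at (x_min, y_max) dominates everything
  s <- bivariate_sample(c(1, 2, 3), c(5, 3, 1))
  expect_equal(find_peers(s, "upper_left"), data.frame(x = 1, y = 5))
  cl <- cefdh_ceiling(s, "upper_left")
  expect_equal(ceiling_area(cl), 0)

  # duplicated points retained once
  sd <- bivariate_sample(c(1, 2, 2, 4), c(1, 3, 3, 5))
  pd <- find_peers(sd, "upper_left")
  expect_equal(nrow(pd), 3)
  expect_false(any(duplicated(pd)))
})

test_that("find_peers agrees with the pairwise dominance oracle", {
  for (i in 1:100) {
    s <- random_sample(5 + (i %% 40), seed = 100 + i,
                       integers = i %% 3 == 0)
    got <- find_peers(s, "upper_left")
    ora <- dominance_peers_oracle(s)
    expect_equal(got$x, ora$x)
    expect_equal(got$y, ora$y)
  }
})

test_that("the CE-FDH step function jumps at peers and is clipped to the scope", {
  cl <- cefdh_ceiling(toy_sample(), "upper_left")
  expect_equal(ceiling_value(cl, c(1, 1.5, 2, 3.9, 4, 5)),
               c(1, 1, 3, 3, 5, 5))
  # left of the first peer (theoretical scope) the first peer's y applies
  st <- bivariate_sample(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4),
                         x_range = c(0, 6), y_range = c(0, 6))
  clt <- cefdh_ceiling(st, "upper_left", scope_mode = "theoretical")
  expect_equal(ceiling_value(clt, 0.5), 1)
})

test_that("ceiling_area matches hand-computed step integrals", {
  expect_equal(ceiling_area(cefdh_ceiling(toy_sample(), "upper_left")), 8)
  # flat ceiling: empty zone vanishes
  s <- bivariate_sample(c(1, 2, 3), c(5, 3, 1))
  expect_equal(ceiling_area(cefdh_ceiling(s, "upper_left")), 0)
  # diagonal staircase on the unit square fills all but the staircase steps
  s2 <- bivariate_sample(c(0, 0.5, 1), c(0, 0.5, 1))
  expect_equal(ceiling_area(cefdh_ceiling(s2, "upper_left")), 0.75)
})

test_that("ceiling_area agrees with the independent column-grid oracle", {
  for (i in 1:25) {
    s <- random_lattice_sample(5 + (i %% 30), seed = 400 + i)
    area <- ceiling_area(cefdh_ceiling(s, "upper_left"))
    cell <- diff(range(s$x)) * diff(range(s$y)) / 2000^2
    expect_lt(abs(area - grid_area_oracle(s)), 2 * cell)
  }
})

test_that("effect_size is the area ratio with domain checks", {
  expect_equal(effect_size(8, 16), 0.5)
  expect_equal(effect_size(0, 7), 0)
  expect_equal(effect_size(7, 7), 1)
  expect_error(effect_size(1, 0), "positive")
  expect_error(effect_size(5, 4), class = "ncafdh_internal_error")
})

test_that("benchmark labels follow the inclusive-lower-bound convention", {
  expect_equal(classify_effect(0), "none")
  expect_equal(classify_effect(0.05), "small")
  expect_equal(classify_effect(0.10), "medium")
  expect_equal(classify_effect(0.25), "medium")
  expect_equal(classify_effect(0.22), "medium")
  expect_equal(classify_effect(0.30), "large")
  expect_equal(classify_effect(0.50), "very_large")
  expect_error(classify_effect(1.2), class = "ncafdh_validation_error")
})

test_that("nca_analyze composes the pieces consistently", {
  est <- nca_analyze(toy_sample(), "upper_left")
  expect_equal(est$d, 0.5)
  expect_equal(est$label, "very_large")
  expect_equal(est$accuracy, 1)
  expect_equal(est$n_used, 5)
  expect_equal(est$ceiling_area / est$scope_area, est$d)
})

test_that("no observation lies above the ceiling; CE-FDH accuracy is exactly 1", {
  for (i in 1:60) {
    s <- random_sample(4 + (i %% 30), seed = 700 + i, integers = i %% 2 == 0)
    for (corner in c("upper_left", "upper_right")) {
      cl <- cefdh_ceiling(s, corner)
      expect_true(all(s$y <= ceiling_value(cl, s$x) + 1e-12))
      expect_equal(nca_analyze(s, corner)$accuracy, 1)
    }
  }
})

test_that("reflection duality: upper_right equals upper_left on x-reflected data", {
  for (i in 1:50) {
    s <- random_sample(5 + (i %% 25), seed = 900 + i, integers = i %% 4 == 0)
    sr <- bivariate_sample(-s$x, s$y)
    expect_identical(nca_analyze(s, "upper_right")$d,
                     nca_analyze(sr, "upper_left")$d)
  }
  # and on the toy sample explicitly
  toy_r <- bivariate_sample(-c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_identical(nca_analyze(toy_r, "upper_right")$d, 0.5)
})

test_that("d is invariant under positive affine rescaling of either axis", {
  for (i in 1:40) {
    s <- random_sample(6 + (i %% 20), seed = 1300 + i)
    tr <- with_seed_local(2000 + i,
                          c(a = runif(1, 0.1, 10), b = runif(1, -5, 5),
                            cc = runif(1, 0.1, 10), e = runif(1, -5, 5)))
    s2 <- bivariate_sample(tr["a"] * s$x + tr["b"],
                           tr["cc"] * s$y + tr["e"])
    expect_lt(abs(nca_analyze(s, "upper_left")$d -
                  nca_analyze(s2, "upper_left")$d), 1e-12)
  }
})

test_that("adding an observation never grows the empty zone (fixed scope)", {
  # New points are drawn at or right of the current minimum x: left of it
  # the ceiling takes the first peer's y by convention, so a fresh
  # leftmost low-y point can legitimately lower the ceiling there.
  for (i in 1:30) {
    with_seed_local(3000 + i, {
      n <- 5 + i %% 20
      x <- runif(n); y <- runif(n)
      s1 <- bivariate_sample(x, y, x_range = c(0, 1), y_range = c(0, 1))
      a1 <- ceiling_area(cefdh_ceiling(s1, "upper_left",
                                       scope_mode = "theoretical"))
      s2 <- bivariate_sample(c(x, runif(1, min(x), 1)), c(y, runif(1)),
                             x_range = c(0, 1), y_range = c(0, 1))
      a2 <- ceiling_area(cefdh_ceiling(s2, "upper_left",
                                       scope_mode = "theoretical"))
      expect_lte(a2, a1 + 1e-12)
    })
  }
})

test_that("the fast resampling path reproduces the full analysis d", {
  for (i in 1:30) {
    s <- random_sample(5 + (i %% 25), seed = 1700 + i, integers = i %% 2 == 0)
    for (corner in c("upper_left", "upper_right")) {
      expect_equal(ncafdh:::cefdh_d_quick(s$x, s$y, corner),
                   nca_analyze(s, corner)$d)
    }
    sb <- bivariate_sample(s$x, s$y, x_range = c(-1, 11), y_range = c(-1, 11))
    expect_equal(ncafdh:::cefdh_d_quick(sb$x, sb$y, "upper_right",
                                        c(-1, 11), c(-1, 11)),
                 nca_analyze(sb, "upper_right", "theoretical")$d)
  }
})
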
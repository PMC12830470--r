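# Shared fixtures and independent oracles used across test files.

toy_sample <- function() {
  bivariate_sample(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4), label = "toy")
}

# Random continuous sample on [0, 10]^2 (with occasional integer rounding
# to exercise ties).
random_sample <- function(n, seed, integers = FALSE) {
  with_seed_local(seed, {
    x <- runif(n, 0, 10)
    y <- runif(n, 0, 10)
    if (integers) { x <- round(x); y <- round(y) }
    if (length(unique(x)) < 2 || length(unique(y)) < 2)
      return(random_sample(n, seed + 1000, integers))
    bivariate_sample(x, y)
  })
}

# Sample whose x coordinates sit exactly on the 2000-column lattice over
# the empirical x range, so the column-sum grid estimate of the empty
# zone is exact (the step function is constant within every column).
random_lattice_sample <- function(n, seed, cells = 2000) {
  with_seed_local(seed, {
    k <- c(0, cells, sample.int(cells + 1, n - 2, replace = TRUE) - 1)
    bivariate_sample(k / cells, runif(n))
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Independent empty-zone area oracle: brute-force FDH evaluation on a
# column grid over the empirical scope (upper-left corner). For each
# column left edge l_j the ceiling is max{y_i : x_i <= l_j}; summing
# column areas gives the exact step integral whenever no jump falls
# strictly inside a column (guaranteed for lattice-aligned x).
grid_area_oracle <- function(sample, cells = 2000) {
  x <- sample$x; y <- sample$y
  x_lo <- min(x); x_hi <- max(x); y_top <- max(y)
  w <- (x_hi - x_lo) / cells
  left <- x_lo + (seq_len(cells) - 1L) * w
  cj <- vapply(left, function(l) max(y[x <= l + 1e-12]), numeric(1))
  sum((y_top - cj) * w)
}

# Independent peer oracle: O(n^2) pairwise dominance scan on distinct
# points (upper-left corner).
dominance_peers_oracle <- function(sample) {
  pts <- unique(data.frame(x = sample$x, y = sample$y))
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    dominators <- pts$x <= pts$x[i] & pts$y >= pts$y[i] &
      !(pts$x == pts$x[i] & pts$y == pts$y[i])
    !any(dominators)
  }, logical(1))
  out <- pts[keep, ]
  out[order(out$x), ]
}

# Exhaustive permutation distribution of d for tiny n (oracle for the
# permutation test's p-value definition).
exact_perm_d <- function(x, y, corner = "upper_left") {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  vapply(perms(x), function(xp) ncafdh:::cefdh_d_quick(xp, y, corner),
         numeric(1))
}
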
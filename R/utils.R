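# Internal helpers: condition classes, seed scoping, argument checks.

abort_validation <- function(msg, class = character()) {
  stop(errorCondition(msg, class = c(class, "ncafdh_validation_error",
                                     "ncafdh_error")))
}

abort_internal <- function(msg) {
  stop(errorCondition(msg, class = c("ncafdh_internal_error", "ncafdh_error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation(sprintf("`%s` must be a single finite number", name))
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok)
    abort_validation(sprintf("`%s` = %g is outside %s%g, %g%s", name, x,
                             if (strict) "(" else "[", lower, upper,
                             if (strict) ")" else "]"))
  if (integer && x != round(x))
    abort_validation(sprintf("`%s` must be an integer", name))
  x
}

check_seed <- function(seed) {
  check_number(seed, "seed", lower = 0, upper = .Machine$integer.max,
               integer = TRUE)
  as.integer(seed)
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Independent sub-seeds derived reproducibly from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(check_seed(seed), sample.int(.Machine$integer.max - 1L, n))
}

match_corner <- function(corner) {
  match.arg(corner, c("upper_left", "upper_right"))
}

match_scope_mode <- function(mode) {
  match.arg(mode, c("empirical", "theoretical"))
}
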
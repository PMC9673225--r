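# Internal helpers shared across modules.

# Run `code` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so no simulator call leaks global state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Coerce class labels to 0/1 integers (1 = positive). Accepts logical,
# numeric 0/1, or a two-level factor/character (the larger level is positive
# only when levels are exactly c("0","1") or logical-like; otherwise error).
check_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) {
      abort("`labels` must be logical or coded 0/1.")
    }
    return(as.integer(labels))
  }
  abort("`labels` must be logical or coded 0/1.")
}

check_both_classes <- function(labels) {
  if (length(unique(labels)) < 2) {
    abort("both classes (positive and negative) must be present.")
  }
  invisible(labels)
}

# Strictly-interior local maxima; ties broken toward the earlier index by
# requiring a strict rise on the left and a non-strict fall on the right.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

moving_average <- function(x, k) {
  if (k < 2) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

# Wilson score interval for a binomial proportion (no continuity correction).
wilson_ci <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}
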
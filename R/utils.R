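# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
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
  expr
}

# Trapezoidal integral of y over x (uniform or non-uniform grid).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Linear interpolation of the crossing time of `level` between samples j and
# j + 1 of series (t, y); assumes y[j] and y[j + 1] straddle the level.
interp_crossing <- function(t, y, j, level) {
  f <- (level - y[j]) / (y[j + 1L] - y[j])
  t[j] + f * (t[j + 1L] - t[j])
}

# Linear interpolation of series y at time tt on grid t (uniform).
interp_at <- function(t, y, tt) {
  stats::approx(t, y, xout = tt, rule = 2)$y
}

# Deterministic per-cell seed derived from a master seed, kept inside the
# 32-bit integer range.
derive_seed <- function(master, ...) {
  idx <- c(...)
  x <- as.double(master)
  for (k in seq_along(idx)) {
    x <- (x * 7919 + as.double(idx[k]) * 104729 + 17) %% 2147483629
  }
  as.integer(x)
}
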
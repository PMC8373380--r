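# Internal helpers shared across modules.

# round-half-up, unlike base round() which rounds half to even
round_half_up <- function(x) floor(x + 0.5)

# Highest-glucose crossing of `y` (evaluated at ascending glucose `g`) with
# `target`, interpolated linearly in log10(glucose). Returns NA when the
# curve never crosses the target within the grid. Noise can make empirical
# curves non-monotone; scanning segments from the top of the titration down
# reads the threshold off the monotone underlying curve.
cross_glucose <- function(g, y, target) {
  ok <- is.finite(y) & is.finite(g)
  g <- g[ok]
  y <- y[ok]
  if (length(g) < 2L) {
    return(NA_real_)
  }
  x <- log10(g)
  for (i in rev(seq_len(length(g) - 1L))) {
    y0 <- y[i] - target
    y1 <- y[i + 1L] - target
    if (y0 == 0) {
      return(g[i])
    }
    if (y1 == 0) {
      return(g[i + 1L])
    }
    if (sign(y0) != sign(y1)) {
      xs <- x[i] + (target - y[i]) * (x[i + 1L] - x[i]) / (y[i + 1L] - y[i])
      return(10^xs)
    }
  }
  NA_real_
}

# run `expr` under a fixed seed when one is given, untouched otherwise
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}
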
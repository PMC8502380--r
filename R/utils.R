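# Internal helpers shared across modules.

# Wrap angles to the half-open interval (-pi, pi]; reversals map to +pi so
# that binning is deterministic.
wrap_angle <- function(a) {
  w <- a %% (2 * pi)           # in [0, 2*pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. With seed = NULL the global stream is used as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Fast simple linear regression y ~ x: slope, intercept, slope SE, R^2.
# Equivalent to lm() but avoids its overhead in tight per-trajectory loops.
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  tss <- sum((y - my)^2)
  se <- if (n > 2) sqrt(rss / (n - 2) / sxx) else NA_real_
  r2 <- if (tss > 0) 1 - rss / tss else 1
  list(slope = slope, intercept = intercept, se = se, r_squared = r2)
}

# %.17g formatting so numeric CSV round-trips are exact to the last bit.
format_full <- function(x) {
  if (is.numeric(x)) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- NA_character_
    out
  } else x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
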
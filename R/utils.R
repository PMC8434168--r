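# Internal helpers shared across modules.

#' Clip values to a closed interval
#' @noRd
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stable 31-bit hash of a string, combined with a root seed, so each
# participant gets a reproducible RNG substream independent of the order in
# which participants are simulated.
stable_hash <- function(id, seed) {
  codes <- utf8ToInt(id)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 7919) %% 2147483647)
}

# Mean of a normal(mu, sd) winsorized at [lo, hi] (censored, not resampled).
censored_normal_mean <- function(mu, sd, lo, hi) {
  if (sd <= 0) return(clip(mu, lo, hi))
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  lo * stats::pnorm(a) + hi * (1 - stats::pnorm(b)) +
    mu * (stats::pnorm(b) - stats::pnorm(a)) +
    sd * (stats::dnorm(a) - stats::dnorm(b))
}

# Location parameter such that a normal(mu*, sd) draw clipped to [lo, hi]
# has expectation `target`. Used to calibrate every published group mean so
# the simulated sample mean converges to the printed value despite
# instrument-bound truncation (e.g. Borg ratings piling up at the bottom of
# the 6-20 scale).
calibrate_location <- function(target, sd, lo, hi) {
  stopifnot(target >= lo, target <= hi)
  if (sd <= 0) return(target)
  f <- function(mu) censored_normal_mean(mu, sd, lo, hi) - target
  span <- 10 * sd + (hi - lo)
  stats::uniroot(f, lower = lo - span, upper = hi + span, tol = 1e-10)$root
}
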
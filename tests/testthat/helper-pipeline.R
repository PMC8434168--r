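# Shared fixtures, built in code at test time.

small_config <- function(seed = 101L, sizes = c(CN = 8L, MCI = 10L, MD = 6L), ...)
  cohort_config(group_sizes = sizes, seed = seed, ...)

# One small simulated pipeline, computed lazily and cached for the session.
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_config()
      cohort <- generate_cohort(cfg)
      plays <- simulate_cohort_sessions(cohort, cfg)
      scores <- score_sessions(plays)
      features <- build_feature_matrix(scores, cohort)
      cache <<- list(cfg = cfg, cohort = cohort, plays = plays,
                     scores = scores, features = features)
    }
    cache
  }
})

# Random association structure realized from an actual discretized dataset,
# i.e. a genuine symmetric-uncertainty matrix.
random_su_assoc <- function(p, n = 60) {
  X <- as.data.frame(matrix(stats::rnorm(n * p), n, p))
  names(X) <- sprintf("f%02d", seq_len(p))
  y <- factor(sample(c("A", "B", "C"), n, replace = TRUE))
  X[[sample.int(p, 1)]] <- stats::rnorm(n) + as.integer(y)
  association_matrix(X, y)
}

# Exhaustive CFS maximum over all non-empty subsets.
exhaustive_cfs_max <- function(assoc) {
  feats <- names(assoc$cf)
  best <- 0
  for (k in seq_along(feats)) {
    cmb <- utils::combn(feats, k)
    for (j in seq_len(ncol(cmb)))
      best <- max(best, cfs_merit(cmb[, j], assoc))
  }
  best
}
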
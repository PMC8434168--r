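test_that("cohort structure follows the configuration", {
  fx <- pipeline_fixture()
  coh <- fx$cohort
  expect_equal(nrow(coh), sum(fx$cfg$group_sizes))
  expect_equal(as.vector(table(coh$group)), unname(fx$cfg$group_sizes))
  expect_false(anyDuplicated(coh$id) > 0)
  expect_true(all(coh$mmse >= 0 & coh$mmse <= 30))
  expect_true(all(coh$moca >= 0 & coh$moca <= 30))
  expect_true(all(coh$tmt_a > 0 & coh$tmt_b > 0))
  ab <- as.matrix(coh[, startsWith(names(coh), "ability_")])
  expect_true(all(ab >= 0 & ab <= 1))
})

test_that("configuration validation rejects invalid inputs", {
  expect_error(cohort_config(group_sizes = c(CN = 0L, MCI = 5L, MD = 5L)), "positive")
  expect_error(cohort_config(promotion_schedule = c(7L, 7L, 19L)), "increasing")
  expect_error(cohort_config(promotion_schedule = integer(0)), "empty")
  expect_error(cohort_config(promotion_schedule = c(5L, 9L, 13L, 17L)), "levels")
  expect_error(cohort_config(sessions_per_week = 5L), "sessions_per_week")
  bad <- default_group_params(); bad$CN$mmse[2] <- -1
  expect_error(cohort_config(group_params = bad), "negative SD")
})

test_that("generation is seed-deterministic with id-keyed substreams", {
  cfg <- small_config(seed = 77L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_false(identical(c1, generate_cohort(small_config(seed = 78L))))
  # a participant's session stream does not depend on the rest of the cohort
  solo <- simulate_sessions(c1[5, ], cfg)
  all_ <- simulate_cohort_sessions(c1, cfg)
  expect_identical(solo, all_[all_$participant_id == c1$id[5], ])
})

test_that("degenerate SDs collapse to the configured means", {
  pars <- default_group_params()
  pars$CN <- lapply(pars$CN, function(p) c(p[1], 0))
  cfg <- cohort_config(group_sizes = c(CN = 50L), group_params = pars,
                       noise_sd = c(strength = 0, aerobic = 0, flexibility = 0,
                                    balance = 0, hrmg = 0, heart_rate = 0, borg = 0),
                       seed = 5L)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$mmse == round(pars$CN$mmse[1])))
  expect_true(all(coh$age == pars$CN$age[1]))
  expect_true(all(coh$baseline_hrmg == pars$CN$hrmg[1]))
})

test_that("session schedule and difficulty promotion", {
  fx <- pipeline_fixture()
  expect_equal(session_levels(24, c(7, 13, 19)),
               rep(1:4, each = 6))
  one <- fx$plays[fx$plays$participant_id == fx$cohort$id[1], ]
  expect_equal(length(unique(one$session_index)),
               fx$cfg$sessions_per_week * fx$cfg$n_weeks)
  by_sess <- tapply(one$level, one$session_index, unique)
  expect_true(all(diff(unlist(by_sess)) >= 0))
  # every session carries at least one play per configured domain
  per <- table(one$session_index, one$domain)
  expect_true(all(per[, c(names(default_game_roster()), "heart_rate", "borg")] >= 1))
})

test_that("noiseless flat generator yields identical recomputed scores", {
  pars <- default_group_params()
  pars$CN <- lapply(pars$CN, function(p) c(p[1], 0))
  pars$CN$hrmg <- c(10, 0)   # boundary ability: emission is deterministic
  cfg <- cohort_config(group_sizes = c(CN = 2L), group_params = pars,
                       learning_slope = c(CN = 0),
                       noise_sd = c(strength = 0, aerobic = 0, flexibility = 0,
                                    balance = 0, hrmg = 0, heart_rate = 0, borg = 0),
                       seed = 3L)
  coh <- generate_cohort(cfg)
  ds <- score_sessions(simulate_cohort_sessions(coh, cfg))
  hrmg <- ds[ds$domain == "hrmg", ]
  expect_true(all(hrmg$score == 10))
  # latent domain scores are flat for every domain when noise and slope are 0
  plays <- simulate_sessions(coh[1, ], cfg)
  flat <- tapply(plays$latent, plays$domain, function(v) length(unique(v)))
  expect_true(all(flat == 1))
})

test_that("noiseless per-level latent trends recover the configured slope exactly", {
  s <- 0.04
  cfg <- small_config(sizes = c(MCI = 3L), seed = 9L,
                      learning_slope = c(MCI = s),
                      noise_sd = c(strength = 0, aerobic = 0, flexibility = 0,
                                   balance = 0, hrmg = 0, heart_rate = 0, borg = 0))
  coh <- generate_cohort(cfg)
  plays <- simulate_sessions(coh[2, ], cfg)
  hrmg <- plays[plays$domain == "hrmg" & plays$game_id == "fishing", ]
  for (lev in 1:4) {
    series <- hrmg$latent[hrmg$level == lev]
    tr <- fit_trend(seq_along(series), series)
    expect_equal(tr$slope, s, tolerance = 1e-12)
    expect_equal(tr$intercept, series[1] - s, tolerance = 1e-12)
  }
})

test_that("raw metric emission is mean-calibrated and respects invariants", {
  set.seed(42)
  # expected unit score equals ability (binomial construction)
  for (g in c("fishing", "golf", "apple", "arkanoid")) {
    u <- replicate(10000, score_game(emit_raw_metrics(0.5, g), g))
    expect_equal(mean(u), 0.5, tolerance = 0.01)
  }
  # boundaries
  m1 <- emit_raw_metrics(1, "fishing")
  expect_equal(m1$caught_fish, 10L)
  expect_equal(score_game(m1, "fishing"), 1)
  m0 <- emit_raw_metrics(0, "fishing")
  expect_equal(m0$caught_fish, 0L)
  expect_equal(score_game(m0, "fishing"), 0)
  for (g in names(GAME_TO_DOMAIN)[1:9])
    expect_equal(score_game(emit_raw_metrics(1, g), g), 1)
  expect_error(emit_raw_metrics(0.5, "ping_pong"), "unknown game_id")
  expect_error(emit_raw_metrics(1.2, "fishing"), "ability")
  # type invariants over random draws, every game
  games <- c("cycling", "strength_reps", "stretching_reps", "steps",
             "apple", "arkanoid", "fishing", "golf", "ski")
  for (g in games) {
    draws <- replicate(2000, emit_raw_metrics(runif(1), g), simplify = FALSE)
    get <- function(f) vapply(draws, function(m) as.numeric(m[[f]]), numeric(1))
    flds <- names(draws[[1]])
    for (f in setdiff(flds, "ball_scored")) expect_true(all(get(f) >= 0))
    if ("caught_fish" %in% flds) expect_true(all(get("caught_fish") <= get("total_fish")))
    if ("apples_gathered" %in% flds) {
      expect_true(all(get("apples_gathered") <= get("total_apples")))
      expect_true(all(get("finish_time") <= get("time_limit")))
    }
    if ("hit_targets" %in% flds) {
      expect_true(all(get("hit_targets") <= get("total_targets")))
      expect_true(all(get("remaining_lives") <= get("total_lives")))
    }
    if ("correct_iterations" %in% flds)
      expect_true(all(get("correct_iterations") <= get("total_iterations")))
    if (g == "ski") expect_true(all(get("distance_travelled") <= get("max_possible_distance")))
    if (g == "golf") expect_true(all(get("distance_travelled") >= get("optimal_path_distance")))
  }
})

test_that("group sample means converge to the calibrated targets", {
  pars <- default_group_params()
  cfg <- cohort_config(group_sizes = c(CN = 5000L), seed = 20260928 %% 100000L)
  coh <- generate_cohort(cfg)
  n <- nrow(coh)
  for (q in c("age", "education", "mmse", "moca", "tmt_a", "tmt_b")) {
    key <- c(age = "age", education = "education", mmse = "mmse", moca = "moca",
             tmt_a = "tmt_a", tmt_b = "tmt_b")[[q]]
    expect_lt(abs(mean(coh[[key]]) - pars$CN[[q]][1]),
              3 * pars$CN[[q]][2] / sqrt(n) + 0.01)  # +0.01 covers integer rounding
  }
  # latent baselines calibrated against the post-clipping session distribution
  expect_lt(abs(mean(clip(coh$baseline_hrmg, 0, 10)) - pars$CN$hrmg[1]),
            3 * pars$CN$hrmg[2] / sqrt(n) + 0.02)
})

test_that("expected baseline ability ranks CN > MCI > MD", {
  cfg <- cohort_config(group_sizes = c(CN = 800L, MCI = 800L, MD = 800L), seed = 17L)
  coh <- generate_cohort(cfg)
  m <- tapply(coh$ability_hrmg, coh$group, mean)
  expect_gt(m[["CN"]], m[["MCI"]])
  expect_gt(m[["MCI"]], m[["MD"]])
})
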
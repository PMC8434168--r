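#' Cohort simulation configuration
#'
#' Builds the configuration object driving the synthetic cohort generator.
#' Defaults reproduce the published trial conditions: a 116-participant
#' cohort (38 cognitively normal, 64 mild cognitive impairment, 14 mild
#' dementia), trained 3 sessions/week for 8 weeks across 4 difficulty
#' levels, with group-level demographics, neuropsychological scores
#' (MMSE, MoCA, Trail Making A/B), baseline exergame domain scores, heart
#' rate and Borg exertion ratings calibrated to the published group
#' means and standard deviations.
#'
#' @param group_sizes named integer vector, participants per diagnostic
#'   group (`CN`, `MCI`, `MD`).
#' @param group_params nested list `group -> quantity -> c(mean, sd)`; see
#'   [default_group_params()]. Quantities: `age`, `education`, `mmse`,
#'   `moca`, `tmt_a`, `tmt_b`, `strength`, `aerobic`, `flexibility`,
#'   `balance`, `hrmg`, `heart_rate`, `borg`, plus `female` (proportion).
#' @param sessions_per_week integer, 3 or 4.
#' @param n_weeks integer, 7 or 8.
#' @param promotion_schedule strictly increasing session indices at which
#'   the difficulty level increments (at most 3 promotions, 4 levels).
#' @param learning_slope named vector, expected score gain per session
#'   within a level, per group (applied to the game domains; vitals and
#'   Borg have no learning trend).
#' @param noise_sd named vector, within-participant session noise SD per
#'   domain (score points for game domains, bpm for heart rate, Borg
#'   points for exertion).
#' @param latent_rho correlation induced by the shared per-participant
#'   cognitive factor between any two loaded quantities (neuropsych tests
#'   and game-domain baselines).
#' @param game_roster named list, games played per domain each session.
#' @param hr_readings number of manual heart-rate readings per session.
#' @param hr_reading_sd measurement SD (bpm) of a single reading around
#'   the session's true heart rate.
#' @param seed root RNG seed; per-participant substreams are derived from
#'   it by hashing participant ids.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(CN = 38L, MCI = 64L, MD = 14L),
                          group_params = default_group_params(),
                          sessions_per_week = 3L,
                          n_weeks = 8L,
                          promotion_schedule = c(7L, 13L, 19L),
                          learning_slope = c(CN = 0.05, MCI = 0.03, MD = 0.02),
                          noise_sd = c(strength = 0.8, aerobic = 0.8,
                                       flexibility = 0.6, balance = 0.8,
                                       hrmg = 0.8, heart_rate = 4, borg = 0.8),
                          latent_rho = 0.6,
                          game_roster = default_game_roster(),
                          hr_readings = 3L,
                          hr_reading_sd = 3,
                          seed = 1L) {
  if (any(group_sizes <= 0)) stop("all group sizes must be positive", call. = FALSE)
  if (!all(names(group_sizes) %in% names(group_params)))
    stop("group_params missing for some groups", call. = FALSE)
  if (!sessions_per_week %in% 3:4) stop("sessions_per_week must be 3 or 4", call. = FALSE)
  if (!n_weeks %in% 7:8) stop("n_weeks must be 7 or 8", call. = FALSE)
  if (length(promotion_schedule) == 0)
    stop("promotion_schedule must not be empty", call. = FALSE)
  if (any(diff(promotion_schedule) <= 0))
    stop("promotion_schedule must be strictly increasing", call. = FALSE)
  if (length(promotion_schedule) > 3)
    stop("at most 4 difficulty levels (3 promotions)", call. = FALSE)
  n_sessions <- sessions_per_week * n_weeks
  if (max(promotion_schedule) > n_sessions)
    stop("promotion beyond the last session", call. = FALSE)
  for (g in names(group_params)) {
    sds <- vapply(group_params[[g]], function(p) p[[2]], numeric(1))
    if (any(sds < 0)) stop("negative SD in group_params", call. = FALSE)
  }
  structure(list(
    group_sizes = group_sizes, group_params = group_params,
    sessions_per_week = as.integer(sessions_per_week),
    n_weeks = as.integer(n_weeks),
    promotion_schedule = as.integer(promotion_schedule),
    learning_slope = learning_slope, noise_sd = noise_sd,
    latent_rho = latent_rho, game_roster = game_roster,
    hr_readings = as.integer(hr_readings), hr_reading_sd = hr_reading_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Published per-group calibration parameters
#'
#' Mean and SD per diagnostic group for demographics, neuropsychological
#' instruments and baseline exergame domain scores, as reported for the
#' trial cohort. `female` is the proportion of women. The balance domain
#' was not reported with a baseline and uses a neutral default.
#'
#' @return nested list `group -> quantity -> c(mean, sd)`.
#' @export
default_group_params <- function() {
  list(
    CN = list(age = c(67.1, 5.2), education = c(8.5, 2.6),
              mmse = c(28.1, 1.2), moca = c(26.2, 2.4),
              tmt_a = c(70.0, 32.3), tmt_b = c(141.9, 64.1),
              strength = c(7.6, 1.2), aerobic = c(6.8, 1.6),
              hrmg = c(5.2, 1.2), flexibility = c(8.7, 1.0),
              balance = c(8.0, 1.0),
              heart_rate = c(74.0, 10.2), borg = c(6.9, 1.2),
              female = c(30 / 38, 0)),
    MCI = list(age = c(69.3, 6.4), education = c(7.6, 2.8),
               mmse = c(26.5, 2.2), moca = c(22.43, 2.9),
               tmt_a = c(86.9, 36.3), tmt_b = c(189.7, 76.5),
               strength = c(7.6, 0.9), aerobic = c(6.4, 1.4),
               hrmg = c(4.7, 0.8), flexibility = c(8.9, 0.4),
               balance = c(7.8, 1.0),
               heart_rate = c(72.6, 9.8), borg = c(7.1, 1.2),
               female = c(54 / 64, 0)),
    MD = list(age = c(77.7, 3.4), education = c(5.8, 4.3),
              mmse = c(21.7, 1.5), moca = c(16.0, 2.3),
              tmt_a = c(178.1, 90.4), tmt_b = c(298.9, 80.1),
              strength = c(6.5, 1.7), aerobic = c(5.8, 1.7),
              hrmg = c(3.3, 0.7), flexibility = c(8.3, 0.9),
              balance = c(7.2, 1.2),
              heart_rate = c(72.0, 9.2), borg = c(7.2, 1.0),
              female = c(11 / 14, 0))
  )
}

#' Default per-session game roster
#'
#' One representative game per physical-exercise domain plus the five
#' high-resolution monitoring games (Apple Tree, Arkanoid, Fishing,
#' Mini Golf, Ski Jump).
#' @return named list `domain -> character vector of game ids`.
#' @export
default_game_roster <- function() {
  list(aerobic = "cycling",
       strength = "strength_reps",
       flexibility = "stretching_reps",
       balance = "steps",
       hrmg = c("apple", "arkanoid", "fishing", "golf", "ski"))
}

GAME_DOMAINS <- c(strength = "strength", aerobic = "aerobic",
                  flexibility = "flexibility", balance = "balance",
                  hrmg = "hrmg")

# Instrument/physiological bounds used for winsorization.
QUANTITY_BOUNDS <- list(
  age = c(55, 100), education = c(0, 25),
  mmse = c(0, 30), moca = c(0, 30),
  tmt_a = c(10, 1800), tmt_b = c(10, 1800),
  strength = c(0, 10), aerobic = c(0, 10), flexibility = c(0, 10),
  balance = c(0, 10), hrmg = c(0, 10),
  heart_rate = c(40, 180), borg = c(6, 20)
)

# Loading sign of each quantity on the shared cognitive factor: cognitive
# instruments and game performance load positively, timed trail-making
# loads negatively (longer = worse), the rest are independent.
FACTOR_SIGN <- c(mmse = 1, moca = 1, tmt_a = -1, tmt_b = -1,
                 strength = 1, aerobic = 1, flexibility = 1,
                 balance = 1, hrmg = 1,
                 age = 0, education = 0, heart_rate = 0, borg = 0)

#' Generate a synthetic cohort
#'
#' Draws one participant per row with demographics, neuropsychological
#' scores and latent baseline ability per exercise domain. A shared
#' per-participant cognitive factor induces correlation (`latent_rho`)
#' between the neuropsychological instruments and game-domain baselines.
#' Continuous quantities are normal draws winsorized at instrument bounds,
#' with the location calibrated so the post-winsorization group mean equals
#' the configured mean. Baseline domain scores (and hence abilities) are
#' calibrated so the *session-1* expected domain score matches the
#' configured group baseline.
#'
#' @param config a [cohort_config()].
#' @return tibble with one row per participant: `id`, `group`, `age`,
#'   `sex`, `education`, `mmse`, `moca`, `tmt_a`, `tmt_b`, hidden latent
#'   baselines `baseline_<domain>` and abilities `ability_<domain>`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- names(config$group_sizes)
  n_total <- sum(config$group_sizes)
  ids <- sprintf("P%03d", seq_len(n_total))
  group_of <- rep(groups, times = config$group_sizes)

  lambda <- sqrt(config$latent_rho)
  # Quantities observed through sessions are clipped only at emission;
  # calibrate their location against the total (between + within) SD.
  extra_sd_of <- function(q)
    if (q %in% c(names(GAME_DOMAINS), "heart_rate", "borg")) config$noise_sd[[q]] else 0
  quantities <- names(QUANTITY_BOUNDS)
  locations <- lapply(stats::setNames(groups, groups), function(g) {
    pars <- config$group_params[[g]]
    vapply(quantities, function(q) {
      b <- QUANTITY_BOUNDS[[q]]
      calibrate_location(pars[[q]][1], sqrt(pars[[q]][2]^2 + extra_sd_of(q)^2),
                         b[1], b[2])
    }, numeric(1))
  })
  domains <- names(GAME_DOMAINS)
  cols <- c("age", "education", "mmse", "moca", "tmt_a", "tmt_b",
            "baseline_heart_rate", "baseline_borg",
            paste0("baseline_", domains))
  M <- matrix(NA_real_, n_total, length(cols), dimnames = list(NULL, cols))
  sex <- character(n_total)
  for (i in seq_len(n_total)) {
    g <- group_of[i]
    pars <- config$group_params[[g]]
    with_seed(stable_hash(ids[i], config$seed), {
      z <- stats::rnorm(1)  # shared cognitive factor
      draw <- function(q, clip_now = TRUE) {
        s <- pars[[q]][2]
        b <- QUANTITY_BOUNDS[[q]]
        sgn <- FACTOR_SIGN[[q]]
        e <- stats::rnorm(1)
        mix <- if (sgn == 0) e else sgn * lambda * z + sqrt(1 - lambda^2) * e
        val <- locations[[g]][[q]] + s * mix
        if (clip_now) clip(val, b[1], b[2]) else val
      }
      M[i, "age"] <- draw("age")
      sex[i] <- if (stats::runif(1) < pars$female[1]) "F" else "M"
      M[i, "education"] <- draw("education")
      M[i, "mmse"] <- round(draw("mmse"))
      M[i, "moca"] <- round(draw("moca"))
      M[i, "tmt_a"] <- draw("tmt_a")
      M[i, "tmt_b"] <- draw("tmt_b")
      M[i, "baseline_heart_rate"] <- draw("heart_rate", clip_now = FALSE)
      M[i, "baseline_borg"] <- draw("borg", clip_now = FALSE)
      for (d in domains)
        M[i, paste0("baseline_", d)] <- draw(d, clip_now = FALSE)
    })
  }
  out <- tibble::as_tibble(as.data.frame(M))
  out <- tibble::add_column(out, id = ids,
                            group = factor(group_of, levels = groups),
                            sex = sex, .before = 1)
  for (d in domains)
    out[[paste0("ability_", d)]] <- clip(out[[paste0("baseline_", d)]] / 10, 0, 1)
  out[, c("id", "group", "age", "sex", "education", "mmse", "moca",
          "tmt_a", "tmt_b", "baseline_heart_rate", "baseline_borg",
          paste0("baseline_", domains), paste0("ability_", domains))]
}

#' Difficulty level of each session under a promotion schedule
#' @param n_sessions total number of sessions.
#' @param promotion_schedule session indices at which the level increments.
#' @return integer vector of levels (1-4), non-decreasing.
#' @export
session_levels <- function(n_sessions, promotion_schedule) {
  lev <- rep(1L, n_sessions)
  for (s in promotion_schedule) lev[seq_len(n_sessions) >= s] <- lev[seq_len(n_sessions) >= s] + 1L
  pmin(lev, 4L)
}

#' Simulate a participant's training sessions
#'
#' Produces the longitudinal telemetry stream for one participant: per
#' session and domain a latent expected score
#' `baseline + slope * (t_level - 1) + noise` (with `t_level` the 1-based
#' session ordinal within the current difficulty level) is clipped to the
#' 10-point scale and converted to a play ability in \[0,1\]; every game on
#' the domain's roster then emits raw in-game metrics whose expected unit
#' score equals that ability. Heart-rate readings, blood pressure and a
#' Borg exertion rating are appended as pseudo-plays.
#'
#' @param participant one row of [generate_cohort()] output.
#' @param config the same [cohort_config()].
#' @return tibble of plays: `participant_id`, `session_index`, `level`,
#'   `domain`, `game_id`, `latent` (the session's latent domain score —
#'   simulator ground truth, not written to the telemetry CSV), `metrics`
#'   (list-column of named raw metrics).
#' @export
simulate_sessions <- function(participant, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"), nrow(participant) == 1)
  n_sessions <- config$sessions_per_week * config$n_weeks
  levels <- session_levels(n_sessions, config$promotion_schedule)
  g <- as.character(participant$group)
  slope <- config$learning_slope[[g]]
  domains <- names(GAME_DOMAINS)

  n_games <- sum(lengths(config$game_roster)) + 2L  # + vitals + borg rows
  with_seed(stable_hash(paste0(participant$id, "/sessions"), config$seed), {
    v_session <- v_level <- integer(n_sessions * n_games)
    v_domain <- v_game <- character(n_sessions * n_games)
    v_latent <- numeric(n_sessions * n_games)
    v_metrics <- vector("list", n_sessions * n_games)
    j <- 0L
    add <- function(t, lev, d, gid, m, latent) {
      j <<- j + 1L
      v_session[j] <<- t; v_level[j] <<- lev
      v_domain[j] <<- d; v_game[j] <<- gid
      v_latent[j] <<- latent; v_metrics[[j]] <<- m
    }
    for (t in seq_len(n_sessions)) {
      lev <- levels[t]
      t_level <- sum(levels[seq_len(t)] == lev)  # ordinal within level
      for (d in domains) {
        mu_t <- participant[[paste0("baseline_", d)]] + slope * (t_level - 1)
        score_latent <- clip(mu_t + stats::rnorm(1, 0, config$noise_sd[[d]]), 0, 10)
        ability <- score_latent / 10
        for (gid in config$game_roster[[d]])
          add(t, lev, d, gid, emit_raw_metrics(ability, gid, lev),
              latent = score_latent)
      }
      hr_session <- participant$baseline_heart_rate +
        stats::rnorm(1, 0, config$noise_sd[["heart_rate"]])
      readings <- clip(hr_session + stats::rnorm(config$hr_readings, 0, config$hr_reading_sd),
                       40, 180)
      add(t, lev, "heart_rate", "vitals",
          c(stats::setNames(as.list(readings),
                            paste0("heart_rate_", seq_along(readings))),
            list(systolic = max(stats::rnorm(1, 125, 10), 60),
                 diastolic = max(stats::rnorm(1, 78, 8), 35))),
          latent = hr_session)
      borg_latent <- clip(participant$baseline_borg +
                            stats::rnorm(1, 0, config$noise_sd[["borg"]]), 6, 20)
      add(t, lev, "borg", "borg", list(borg = round(borg_latent)),
          latent = borg_latent)
    }
    tibble::tibble(participant_id = participant$id,
                   session_index = v_session, level = v_level,
                   domain = v_domain, game_id = v_game,
                   latent = v_latent, metrics = v_metrics)
  })
}

#' Simulate telemetry for a whole cohort
#' @param cohort output of [generate_cohort()].
#' @param config the [cohort_config()].
#' @return plays tibble, all participants stacked.
#' @export
simulate_cohort_sessions <- function(cohort, config = cohort_config()) {
  dplyr::bind_rows(lapply(seq_len(nrow(cohort)), function(i)
    simulate_sessions(cohort[i, ], config)))
}

#' Emit raw in-game metrics for one play
#'
#' Inverse of the scoring equations: counts and times are drawn so that
#' the expected unit score of the play equals `ability`. Count metrics are
#' binomial (e.g. fish caught out of 10 at success probability `ability`);
#' continuous ratios use a binomial(100)/100 fraction. For Mini Golf the
#' scorer zeroes the time term when the ball is not scored, so the
#' path-term success probability is inflated by `(a - a^2)/7` to keep the
#' overall expectation exactly `a`.
#'
#' @param ability success probability in \[0,1\].
#' @param game_id one of `cycling`, `strength_reps`, `stretching_reps`,
#'   `steps`, `apple`, `arkanoid`, `fishing`, `golf`, `ski`.
#' @param level difficulty level (kept for provenance; scoring is
#'   level-normalized so emission is level-invariant).
#' @return named list of raw metrics.
#' @export
emit_raw_metrics <- function(ability, game_id, level = 1L) {
  if (!is.finite(ability) || ability < 0 || ability > 1)
    stop("ability must be in [0,1]", call. = FALSE)
  frac <- function(p) stats::rbinom(1, 100, p) / 100
  switch(game_id,
    cycling = list(distance_travelled = 1000 * frac(ability),
                   total_distance = 1000),
    strength_reps = ,
    stretching_reps = ,
    steps = list(correct_iterations = stats::rbinom(1, 10, ability),
                 total_iterations = 10L),
    fishing = list(caught_fish = stats::rbinom(1, 10, ability),
                   total_fish = 10L),
    ski = list(distance_travelled = 100 * frac(ability),
               max_possible_distance = 100),
    apple = list(finish_time = 60 * (1 - frac(ability)), time_limit = 60,
                 apples_gathered = stats::rbinom(1, 10, ability),
                 total_apples = 10L),
    arkanoid = list(hit_targets = stats::rbinom(1, 10, ability),
                    total_targets = 10L,
                    remaining_lives = stats::rbinom(1, 5, ability),
                    total_lives = 5L),
    golf = {
      p_path <- min(1, ability + (ability - ability^2) / 7)
      f <- frac(p_path)
      list(distance_travelled = if (f >= 0.01) 50 / f else 50 * 100,
           optimal_path_distance = 50,
           ball_scored = stats::runif(1) < ability,
           time_to_score = 90 * (1 - frac(ability)),
           total_time = 90)
    },
    stop("unknown game_id: ", game_id, call. = FALSE)
  )
}
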
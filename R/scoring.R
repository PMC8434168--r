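#' Unit score of one game play
#'
#' Evaluates the weighted scoring equation of the given game on its raw
#' in-game metrics, returning a unit score clipped to \[0,1\]. Equations
#' (weights sum to 1 so perfect play scores exactly 1):
#' * aerobic (`cycling`): distance travelled / total distance;
#' * `strength_reps` / `stretching_reps` / `steps`: correct / total
#'   iterations;
#' * `apple`: 0.8 x remaining-time fraction + 0.2 x apples gathered /
#'   total apples;
#' * `arkanoid`: 0.4 x targets hit / total + 0.6 x lives remaining /
#'   total lives;
#' * `fishing`: fish caught / total fish;
#' * `golf`: 0.7 x optimal-path ratio + 0.2 x ball scored + 0.1 x
#'   remaining-time fraction (0 when the ball is not scored);
#' * `ski`: distance travelled / maximum possible distance.
#'
#' Time terms are remaining-time fractions (faster completion scores
#' higher); the golf path term is `optimal / max(travelled, optimal)` so
#' deviation from the optimal path penalizes.
#'
#' @param raw named list of raw metrics (see [emit_raw_metrics()]).
#' @param game_id game identifier.
#' @return unit score in \[0,1\].
#' @export
score_game <- function(raw, game_id) {
  den <- function(sym) {
    v <- raw[[sym]]
    if (is.null(v) || !is.finite(v) || v <= 0)
      stop("zero or missing denominator: ", sym, call. = FALSE)
    v
  }
  u <- switch(game_id,
    cycling = raw$distance_travelled / den("total_distance"),
    strength_reps = ,
    stretching_reps = ,
    steps = raw$correct_iterations / den("total_iterations"),
    fishing = raw$caught_fish / den("total_fish"),
    ski = raw$distance_travelled / den("max_possible_distance"),
    apple = {
      tl <- den("time_limit")
      0.8 * clip((tl - raw$finish_time) / tl, 0, 1) +
        0.2 * raw$apples_gathered / den("total_apples")
    },
    arkanoid = 0.4 * raw$hit_targets / den("total_targets") +
      0.6 * raw$remaining_lives / den("total_lives"),
    golf = {
      opt <- den("optimal_path_distance")
      tt <- den("total_time")
      scored <- isTRUE(raw$ball_scored)
      0.7 * opt / max(raw$distance_travelled, opt) +
        0.2 * scored +
        0.1 * (if (scored) clip((tt - raw$time_to_score) / tt, 0, 1) else 0)
    },
    stop("unknown game_id: ", game_id, call. = FALSE)
  )
  clip(u, 0, 1)
}

#' Normalize a unit score to the 10-point scale
#' @param unit unit score; clipped to \[0,1\] first.
#' @return score in \[0,10\].
#' @export
normalize_score <- function(unit) 10 * clip(unit, 0, 1)

#' Aggregate one session's plays into per-domain scores
#'
#' Game domains get the unweighted mean of the session's normalized game
#' scores; the heart-rate pseudo-domain gets the mean of the session's
#' heart-rate readings (bpm); the Borg pseudo-domain the session's
#' exertion rating. Domains with no plays are absent from the output.
#'
#' @param plays tibble of plays for a single (participant, session).
#' @return tibble: `participant_id`, `session_index`, `level`, `domain`,
#'   `score`.
#' @export
aggregate_session <- function(plays) {
  stopifnot(nrow(plays) >= 1,
            length(unique(plays$session_index)) == 1,
            length(unique(plays$participant_id)) == 1)
  score_sessions(plays)
}

# Per-play contribution: normalized game score, mean heart-rate reading,
# or the Borg rating.
play_value <- function(metrics, game_id, domain) {
  if (domain == "heart_rate")
    mean(unlist(metrics[startsWith(names(metrics), "heart_rate")]))
  else if (domain == "borg") metrics$borg
  else normalize_score(score_game(metrics, game_id))
}

#' Score every session in a plays stream
#' @param plays tibble from [simulate_cohort_sessions()] (any number of
#'   participants/sessions).
#' @return long tibble of per-session domain scores, one row per
#'   (participant, session, domain), in chronological order.
#' @export
score_sessions <- function(plays) {
  vals <- vapply(seq_len(nrow(plays)), function(i)
    play_value(plays$metrics[[i]], plays$game_id[i], plays$domain[i]),
    numeric(1))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(participant_id = plays$participant_id,
                                   session_index = plays$session_index,
                                   level = plays$level,
                                   domain = plays$domain, value = vals),
                    participant_id, session_index, level, domain),
    score = mean(value), .groups = "drop")
  dplyr::arrange(out, participant_id, session_index,
                 match(domain, unique(plays$domain)))
}
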
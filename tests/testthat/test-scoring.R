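test_that("game scoring equations match hand-computed values", {
  expect_equal(score_game(list(caught_fish = 7, total_fish = 10), "fishing"), 0.7)
  expect_equal(score_game(list(hit_targets = 10, total_targets = 10,
                               remaining_lives = 5, total_lives = 5), "arkanoid"), 1.0)
  # finished at half the time limit, 5/10 apples -> 0.8*0.5 + 0.2*0.5
  expect_equal(score_game(list(finish_time = 30, time_limit = 60,
                               apples_gathered = 5, total_apples = 10), "apple"), 0.5)
  expect_equal(score_game(list(distance_travelled = 680, total_distance = 1000),
                          "cycling"), 0.68)
  expect_equal(score_game(list(distance_travelled = 55, max_possible_distance = 100),
                          "ski"), 0.55)
  expect_equal(score_game(list(correct_iterations = 9, total_iterations = 10),
                          "strength_reps"), 0.9)
  # golf: on the optimal path, scored instantly -> every term maximal
  expect_equal(score_game(list(distance_travelled = 50, optimal_path_distance = 50,
                               ball_scored = TRUE, time_to_score = 0,
                               total_time = 90), "golf"), 1.0)
  # not scored: ball and time terms vanish
  expect_equal(score_game(list(distance_travelled = 100, optimal_path_distance = 50,
                               ball_scored = FALSE, time_to_score = 90,
                               total_time = 90), "golf"), 0.35)
})

test_that("scoring errors name the offending denominator", {
  expect_error(score_game(list(caught_fish = 1, total_fish = 0), "fishing"),
               "total_fish")
  expect_error(score_game(list(distance_travelled = 10), "cycling"),
               "total_distance")
  expect_error(score_game(list(), "quidditch"), "unknown game_id")
})

test_that("unit scores clip to [0,1] and normalize linearly to [0,10]", {
  # telemetry noise beyond the valid range is clipped, not rejected
  expect_equal(score_game(list(caught_fish = 12, total_fish = 10), "fishing"), 1)
  expect_equal(score_game(list(finish_time = 90, time_limit = 60,
                               apples_gathered = 0, total_apples = 10), "apple"), 0)
  expect_equal(normalize_score(0), 0)
  expect_equal(normalize_score(1), 10)
  expect_equal(normalize_score(0.47), 4.7)
  expect_equal(normalize_score(1.3), 10)
  expect_equal(normalize_score(-2), 0)
})

test_that("unit scores are monotone in each achievement metric", {
  grids <- list(
    fishing = list(base = list(total_fish = 10), vary = "caught_fish", to = 0:10),
    arkanoid = list(base = list(total_targets = 10, remaining_lives = 2,
                                total_lives = 5), vary = "hit_targets", to = 0:10),
    apple = list(base = list(finish_time = 30, time_limit = 60, total_apples = 10),
                 vary = "apples_gathered", to = 0:10),
    ski = list(base = list(max_possible_distance = 100),
               vary = "distance_travelled", to = seq(0, 100, 10)),
    cycling = list(base = list(total_distance = 1000),
                   vary = "distance_travelled", to = seq(0, 1000, 100)))
  for (g in names(grids)) {
    spec <- grids[[g]]
    u <- vapply(spec$to, function(v) {
      raw <- spec$base; raw[[spec$vary]] <- v
      score_game(raw, g)
    }, numeric(1))
    expect_true(all(diff(u) >= 0), info = g)
  }
  # arkanoid lives; apple speed; golf path deviation penalizes
  lives <- vapply(0:5, function(v) score_game(list(hit_targets = 5, total_targets = 10,
    remaining_lives = v, total_lives = 5), "arkanoid"), numeric(1))
  expect_true(all(diff(lives) >= 0))
  faster <- vapply(seq(60, 0, -10), function(ft) score_game(list(finish_time = ft,
    time_limit = 60, apples_gathered = 5, total_apples = 10), "apple"), numeric(1))
  expect_true(all(diff(faster) >= 0))
  path <- vapply(c(50, 60, 80, 120, 500), function(dtr) score_game(list(
    distance_travelled = dtr, optimal_path_distance = 50, ball_scored = TRUE,
    time_to_score = 45, total_time = 90), "golf"), numeric(1))
  expect_true(all(diff(path) <= 0))
})

test_that("session aggregation takes unweighted means per domain", {
  mk <- function(domain, game_id, metrics)
    tibble::tibble(participant_id = "X", session_index = 1L, level = 1L,
                   domain = domain, game_id = game_id, metrics = list(metrics))
  plays <- dplyr::bind_rows(
    mk("hrmg", "fishing", list(caught_fish = 4, total_fish = 10)),
    mk("hrmg", "arkanoid", list(hit_targets = 0, total_targets = 10,
                                remaining_lives = 5, total_lives = 5)),
    mk("aerobic", "cycling", list(distance_travelled = 680, total_distance = 1000)),
    mk("heart_rate", "vitals", list(heart_rate_1 = 70, heart_rate_2 = 74,
                                    heart_rate_3 = 78, systolic = 120, diastolic = 80)),
    mk("borg", "borg", list(borg = 8)))
  ds <- aggregate_session(plays)
  expect_equal(ds$score[ds$domain == "hrmg"], mean(c(4, 6)))
  expect_equal(ds$score[ds$domain == "aerobic"], 6.8)
  expect_equal(ds$score[ds$domain == "heart_rate"], 74)   # BP is not averaged in
  expect_equal(ds$score[ds$domain == "borg"], 8)
  expect_false("flexibility" %in% ds$domain)  # absent, not zero
})

test_that("all game-domain session scores stay on the 10-point scale", {
  fx <- pipeline_fixture()
  game <- fx$scores[!fx$scores$domain %in% c("heart_rate", "borg"), ]
  expect_true(all(game$score >= 0 & game$score <= 10))
  expect_true(all(fx$scores$score[fx$scores$domain == "borg"] >= 6))
})
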
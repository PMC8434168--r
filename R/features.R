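#' Mean/slope/intercept trend of a score series
#'
#' Summarizes a session-by-session score series by its arithmetic mean and
#' the ordinary least-squares line `score = a * session + b`. The slope is
#' the per-session performance change speed; the intercept estimates
#' performance at session 0. With a single session the line is
#' unidentified and slope/intercept are `NA`.
#'
#' @param session_index strictly increasing session ordinals.
#' @param score scores at those sessions.
#' @return list: `mean`, `slope`, `intercept`, `n_sessions`.
#' @export
fit_trend <- function(session_index, score) {
  n <- length(score)
  if (n == 0) stop("empty series", call. = FALSE)
  if (length(session_index) != n) stop("length mismatch", call. = FALSE)
  if (n > 1 && any(diff(session_index) <= 0))
    stop("session_index must be strictly increasing", call. = FALSE)
  m <- mean(score)
  if (n < 2) return(list(mean = m, slope = NA_real_, intercept = NA_real_,
                         n_sessions = n))
  a <- stats::cov(session_index, score) / stats::var(session_index)
  b <- m - a * mean(session_index)
  list(mean = m, slope = a, intercept = b, n_sessions = n)
}

FEATURE_DOMAINS <- c(strength = "Strength", aerobic = "Aerobic",
                     flexibility = "Flexibility", balance = "Balance",
                     hrmg = "HRMG", heart_rate = "HeartRate", borg = "Borg")

#' Feature names for one domain
#' @noRd
domain_feature_names <- function(label) {
  periods <- c("Total", paste0("Level", 1:4))
  as.vector(vapply(periods, function(p)
    paste0(label, c("Mean", "Slope", "Intercept"), p), character(3)))
}

#' Build one participant's feature vector
#'
#' For each domain, fits [fit_trend()] over the whole training period
#' (`Total`, using the global session index) and within each difficulty
#' level (`Level1`..`Level4`, using the within-level session ordinal
#' 1, 2, ... so that intercepts estimate level-entry performance). Feature
#' names follow the `<Domain><Statistic><Period>` convention, e.g.
#' `HRMGMeanTotal`, `HeartRateSlopeLevel3`. Levels a participant never
#' played yield `NA` features, never zeros.
#'
#' @param domain_scores per-session domain scores for one participant,
#'   chronologically ordered (from [score_sessions()]).
#' @param participant the matching row of the cohort table (for `Age` and
#'   the group label); may be `NULL`.
#' @param domains domains to featurize (defaults to all but balance,
#'   which is scored but not part of the published aggregate).
#' @return one-row tibble: `participant_id`, `Age`, features, `label`.
#' @export
build_feature_vector <- function(domain_scores, participant = NULL,
                                 domains = setdiff(names(FEATURE_DOMAINS), "balance")) {
  if (nrow(domain_scores) == 0) stop("participant has zero sessions", call. = FALSE)
  stopifnot(length(unique(domain_scores$participant_id)) == 1)
  out <- list(participant_id = domain_scores$participant_id[1])
  if (!is.null(participant)) out$Age <- participant$age
  for (d in domains) {
    lab <- FEATURE_DOMAINS[[d]]
    sub <- domain_scores[domain_scores$domain == d, ]
    blocks <- stats::setNames(rep(list(NULL), 5), c("Total", paste0("Level", 1:4)))
    if (nrow(sub) > 0) {
      blocks$Total <- fit_trend(sub$session_index, sub$score)
      for (lev in 1:4) {
        lv <- sub[sub$level == lev, ]
        if (nrow(lv) > 0)
          blocks[[paste0("Level", lev)]] <- fit_trend(seq_len(nrow(lv)), lv$score)
      }
    }
    for (p in names(blocks)) {
      tr <- blocks[[p]]
      out[[paste0(lab, "Mean", p)]] <- if (is.null(tr)) NA_real_ else tr$mean
      out[[paste0(lab, "Slope", p)]] <- if (is.null(tr)) NA_real_ else tr$slope
      out[[paste0(lab, "Intercept", p)]] <- if (is.null(tr)) NA_real_ else tr$intercept
    }
  }
  if (!is.null(participant)) out$label <- as.character(participant$group)
  tibble::as_tibble(out)
}

#' Build the cohort feature matrix
#'
#' @param domain_scores long per-session domain scores for the cohort.
#' @param cohort the cohort table from [generate_cohort()].
#' @param domains see [build_feature_vector()].
#' @return wide tibble, one row per participant with `Age`, all trend
#'   features and the diagnostic `label`.
#' @export
build_feature_matrix <- function(domain_scores, cohort,
                                 domains = setdiff(names(FEATURE_DOMAINS), "balance")) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$id[i]
    build_feature_vector(domain_scores[domain_scores$participant_id == pid, ],
                         cohort[i, ], domains)
  })
  out <- dplyr::bind_rows(rows)
  out$label <- factor(out$label, levels = levels(cohort$group))
  out
}

#' Names of the feature columns in a feature matrix
#' @param features a feature matrix tibble.
#' @return character vector (everything except id and label).
#' @export
feature_names <- function(features)
  setdiff(names(features), c("participant_id", "label"))
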
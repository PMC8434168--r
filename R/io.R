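#' Write the participants table
#'
#' Public CSV interface: one row per participant with demographics and
#' neuropsychological scores (latent simulator columns are dropped).
#' @param cohort tibble from [generate_cohort()].
#' @param path output CSV path.
#' @export
write_participants_csv <- function(cohort, path) {
  out <- tibble::tibble(id = cohort$id, group = as.character(cohort$group),
                        age = cohort$age, sex = cohort$sex,
                        education_years = cohort$education,
                        mmse = cohort$mmse, moca = cohort$moca,
                        tmt_a_s = cohort$tmt_a, tmt_b_s = cohort$tmt_b)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a participants table
#' @param path CSV written by [write_participants_csv()].
#' @return tibble with `group` as a CN/MCI/MD factor and the column names
#'   used internally (`education`, `tmt_a`, `tmt_b`).
#' @export
read_participants_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  tibble::tibble(id = df$id, group = factor(df$group, levels = c("CN", "MCI", "MD")),
                 age = df$age, sex = df$sex, education = df$education_years,
                 mmse = df$mmse, moca = df$moca,
                 tmt_a = df$tmt_a_s, tmt_b = df$tmt_b_s)
}

#' Write session telemetry in long format
#'
#' One row per raw metric: `participant_id`, `session_index`, `level`,
#' `game_id`, `metric_name`, `metric_value`. Vitals and the Borg rating
#' appear as pseudo-games `vitals` and `borg`.
#' @param plays plays tibble from [simulate_cohort_sessions()].
#' @param path output CSV path.
#' @export
write_sessions_csv <- function(plays, path) {
  rows <- lapply(seq_len(nrow(plays)), function(i) {
    m <- plays$metrics[[i]]
    tibble::tibble(participant_id = plays$participant_id[i],
                   session_index = plays$session_index[i],
                   level = plays$level[i], game_id = plays$game_id[i],
                   metric_name = names(m),
                   metric_value = as.numeric(unlist(m)))
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}

GAME_TO_DOMAIN <- c(cycling = "aerobic", strength_reps = "strength",
                    stretching_reps = "flexibility", steps = "balance",
                    apple = "hrmg", arkanoid = "hrmg", fishing = "hrmg",
                    golf = "hrmg", ski = "hrmg",
                    vitals = "heart_rate", borg = "borg")

#' Read session telemetry from the long CSV format
#' @param path CSV written by [write_sessions_csv()].
#' @return plays tibble (metrics re-nested; boolean metrics restored).
#' @export
read_sessions_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  key <- paste(df$participant_id, df$session_index, df$game_id, sep = "\r")
  idx <- split(seq_len(nrow(df)), key)[unique(key)]
  dplyr::bind_rows(lapply(idx, function(i) {
    m <- as.list(df$metric_value[i])
    names(m) <- df$metric_name[i]
    if (!is.null(m$ball_scored)) m$ball_scored <- m$ball_scored != 0
    gid <- df$game_id[i[1]]
    tibble::tibble(participant_id = df$participant_id[i[1]],
                   session_index = df$session_index[i[1]],
                   level = df$level[i[1]],
                   domain = unname(GAME_TO_DOMAIN[gid]),
                   game_id = gid, metrics = list(m))
  }))
}

#' Read a cohort configuration from a YAML file
#'
#' The file may set any subset of [cohort_config()]'s arguments; list
#' entries (`group_params`, `game_roster`) replace the defaults wholesale
#' when given.
#' @param path YAML file.
#' @return a `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  scalar <- function(x) if (is.list(x)) unlist(x) else x
  for (nm in intersect(names(raw), names(formals(cohort_config)))) {
    args[[nm]] <- switch(nm,
      group_sizes = , learning_slope = , noise_sd = scalar(raw[[nm]]),
      group_params = lapply(raw[[nm]], function(g) lapply(g, unlist)),
      game_roster = lapply(raw[[nm]], unlist),
      raw[[nm]])
  }
  do.call(cohort_config, args)
}

#' Write a classifier report to JSON
#' @param report a `classifier_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(list(
    confusion = as.matrix(unclass(report$confusion)),
    classes = report$per_class$class,
    per_class = report$per_class,
    overall_accuracy = report$overall_accuracy,
    selected_features = report$selected_features
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
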
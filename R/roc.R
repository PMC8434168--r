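#' ROC curve and trapezoidal AUC
#'
#' Builds the empirical ROC curve with one operating point per distinct
#' score (ties contribute diagonal segments) and the trapezoidal area
#' under it, which equals the tie-corrected rank-sum concordance
#' probability. `direction` states which end of the score flags the
#' positive class; for cognitive instruments and game scores the impaired
#' (positive) class scores lower.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector, `TRUE` = positive class.
#' @param direction `"higher_is_positive"` or `"lower_is_positive"`.
#' @return list of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `n_pos`, `n_neg`, `direction`.
#' @export
roc_curve <- function(scores, labels,
                      direction = c("higher_is_positive", "lower_is_positive")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (any(!is.finite(scores))) stop("non-finite scores", call. = FALSE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present", call. = FALSE)
  s <- if (direction == "lower_is_positive") -scores else scores
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; lab <- labels[ord]
  # one operating point per distinct score value (most to least strict)
  last <- c(diff(s) != 0, TRUE)
  tp <- cumsum(lab)[last]
  fp <- cumsum(!lab)[last]
  thr <- if (direction == "lower_is_positive") -s[last] else s[last]
  structure(list(thresholds = thr,
                 tpr = c(0, tp / n_pos), fpr = c(0, fp / n_neg),
                 auc = sum(diff(c(0, fp / n_neg)) *
                             (utils::head(c(0, tp / n_pos), -1) +
                                utils::tail(c(0, tp / n_pos), -1)) / 2),
                 n_pos = n_pos, n_neg = n_neg, direction = direction),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d positive / %d negative, %s)\n",
              x$auc, x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

#' Confusion counts at a fixed screening cutoff
#'
#' Thresholds the score into a binary screen: with
#' `"higher_is_positive"`, scores at or above the cutoff are flagged
#' positive; with `"lower_is_positive"`, scores strictly below the cutoff
#' are flagged (the convention of instrument cutoffs such as MoCA < 26).
#'
#' @inheritParams roc_curve
#' @param cutoff threshold value.
#' @return list: `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `accuracy` (proportion).
#' @export
screen_at_cutoff <- function(scores, labels, cutoff,
                             direction = c("higher_is_positive", "lower_is_positive")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (sum(labels) == 0 || sum(!labels) == 0)
    stop("both classes must be present", call. = FALSE)
  flag <- if (direction == "higher_is_positive") scores >= cutoff else scores < cutoff
  tp <- sum(flag & labels); fp <- sum(flag & !labels)
  fn <- sum(!flag & labels); tn <- sum(!flag & !labels)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(labels))
}

#' MCI-vs-CN screening comparison of game metrics and instruments
#'
#' Restricts the cohort to the MCI (positive) and cognitively normal
#' (negative) groups and compares three screens by ROC: the in-game
#' score — either the classifier's out-of-fold MCI probability
#' (`mode = "classifier"`) or the raw total-period HRMG mean
#' (`mode = "hrmg_mean"`) — against MMSE and MoCA at their conventional
#' cutoffs (impairment flagged below 27 and 26 points respectively).
#'
#' @param features feature matrix with `label`.
#' @param cohort cohort table with `mmse`, `moca`.
#' @param mode game-score definition, `"classifier"` or `"hrmg_mean"`.
#' @param seed seed for the classifier cross-validation.
#' @param k folds for the classifier mode.
#' @param mmse_cutoff,moca_cutoff screening cutoffs (scores strictly
#'   below flag impairment).
#' @param ... passed to [cross_validate()] in classifier mode.
#' @return list: `roc` (named list of `roc_result`), `screen` (cutoff
#'   confusion for MMSE/MoCA and the game score at its best-accuracy
#'   threshold), `scores` (tibble of the scores compared).
#' @export
mci_screening <- function(features, cohort, mode = c("classifier", "hrmg_mean"),
                          seed = 1L, k = 10L, mmse_cutoff = 27, moca_cutoff = 26,
                          ...) {
  mode <- match.arg(mode)
  keep <- features$label %in% c("CN", "MCI")
  feats <- features[keep, ]
  merged <- dplyr::inner_join(feats[, "participant_id"],
                              cohort[, c("id", "mmse", "moca")],
                              by = c(participant_id = "id"))
  pos <- feats$label == "MCI"
  game_score <- if (mode == "hrmg_mean") {
    list(values = feats$HRMGMeanTotal, direction = "lower_is_positive")
  } else {
    y2 <- droplevels(factor(feats$label, levels = c("CN", "MCI")))
    rep2 <- cross_validate(feats[, feature_names(feats)], y2, k = k, seed = seed, ...)
    list(values = rep2$probs[, "MCI"], direction = "higher_is_positive")
  }
  roc <- list(
    game = roc_curve(game_score$values, pos, game_score$direction),
    mmse = roc_curve(merged$mmse, pos, "lower_is_positive"),
    moca = roc_curve(merged$moca, pos, "lower_is_positive"))
  # game screen at the accuracy-maximizing observed threshold
  accs <- vapply(roc$game$thresholds, function(th)
    screen_at_cutoff(game_score$values, pos, th, game_score$direction)$accuracy,
    numeric(1))
  best_th <- roc$game$thresholds[which.max(accs)]
  screen <- list(
    game = screen_at_cutoff(game_score$values, pos, best_th, game_score$direction),
    mmse = screen_at_cutoff(merged$mmse, pos, mmse_cutoff, "lower_is_positive"),
    moca = screen_at_cutoff(merged$moca, pos, moca_cutoff, "lower_is_positive"))
  screen$game$cutoff <- best_th
  list(roc = roc, screen = screen,
       scores = tibble::tibble(participant_id = feats$participant_id,
                               mci = pos, game = game_score$values,
                               mmse = merged$mmse, moca = merged$moca))
}
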
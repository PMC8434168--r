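#' Kruskal-Wallis omnibus test with epsilon-squared effect size
#'
#' Tie-corrected Kruskal-Wallis H on mid-ranks with the chi-square
#' approximation (df = k - 1), plus the rank epsilon-squared effect size
#' `H / (n - 1)`, which ranges from 0 (no separation) to 1 (perfect
#' separation without ties). Degenerate input where every observation is
#' identical returns H = 0, p = 1, epsilon-squared = 0.
#'
#' @param values_by_group named list, one numeric vector per group.
#' @return list: `H`, `df`, `p`, `epsilon_sq`, `n`.
#' @export
kruskal_wallis <- function(values_by_group) {
  if (length(values_by_group) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(values_by_group)
  if (any(sizes == 0)) stop("every group needs at least one observation", call. = FALSE)
  x <- unlist(values_by_group, use.names = FALSE)
  n <- length(x)
  k <- length(values_by_group)
  if (length(unique(x)) == 1)
    return(list(H = 0, df = k - 1L, p = 1, epsilon_sq = 0, n = n))
  g <- factor(rep(names(values_by_group), sizes), levels = names(values_by_group))
  kt <- stats::kruskal.test(x, g)
  H <- unname(kt$statistic)
  list(H = H, df = unname(kt$parameter), p = kt$p.value,
       epsilon_sq = H / (n - 1), n = n)
}

#' Dunn's pairwise post-hoc comparisons on pooled ranks
#'
#' Two-sided z-tests on pooled-rank means with tie correction, adjusted
#' for the number of pairs (Bonferroni by default), capped at 1.
#'
#' @param values_by_group named list, one numeric vector per group.
#' @param method multiplicity adjustment passed to [stats::p.adjust()].
#' @return tibble: `group_a`, `group_b`, `z`, `p_raw`, `p_adj`.
#' @export
pairwise_posthoc <- function(values_by_group, method = "bonferroni") {
  if (length(values_by_group) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(values_by_group)
  if (any(sizes == 0)) stop("every group needs at least one observation", call. = FALSE)
  x <- unlist(values_by_group, use.names = FALSE)
  n <- length(x)
  r <- rank(x)
  grp <- rep(names(values_by_group), sizes)
  rbar <- tapply(r, grp, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_term
  pairs <- utils::combn(names(values_by_group), 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(v0 * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z[j] <- if (se == 0) 0 else (rbar[[a]] - rbar[[b]]) / se
    p_raw[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  tibble::tibble(group_a = pairs[1, ], group_b = pairs[2, ], z = z,
                 p_raw = p_raw, p_adj = stats::p.adjust(p_raw, method))
}

#' Pearson correlation with t-test p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3), finite values.
#' @return list: `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Normality check (Shapiro-Wilk or Lilliefors Kolmogorov-Smirnov)
#'
#' Used to annotate which branch (parametric or non-parametric) the
#' pipeline reports for a variable. The Kolmogorov-Smirnov variant tests
#' against a normal with estimated parameters (Lilliefors correction, the
#' convention of standard statistics suites).
#'
#' @param values numeric vector, n >= 3 (>= 4 for Kolmogorov-Smirnov).
#' @param test `"shapiro_wilk"` or `"kolmogorov_smirnov"`.
#' @return list: `statistic`, `p`.
#' @export
normality_check <- function(values, test = c("shapiro_wilk", "kolmogorov_smirnov")) {
  test <- match.arg(test)
  if (length(values) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(values) == 0) stop("degenerate input: constant values", call. = FALSE)
  res <- switch(test,
    shapiro_wilk = stats::shapiro.test(values),
    kolmogorov_smirnov = nortest::lillie.test(values))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Kruskal-Wallis screen of every feature against the diagnosis
#'
#' Runs the omnibus test with epsilon-squared and Dunn-Bonferroni pairwise
#' comparisons for every feature column, sorted by omnibus p.
#'
#' @param features feature matrix from [build_feature_matrix()].
#' @param label_col name of the class column.
#' @return tibble: `feature`, `H`, `df`, `p`, `epsilon_sq` and one
#'   adjusted-p column per group pair (`p_CN_MCI`, ...); features with
#'   missing values are tested on complete cases.
#' @export
screen_features <- function(features, label_col = "label") {
  labs <- features[[label_col]]
  rows <- lapply(feature_names(features), function(f) {
    v <- features[[f]]
    ok <- is.finite(v)
    vg <- split(v[ok], labs[ok])
    if (any(lengths(vg) == 0) || length(unique(v[ok])) < 2) return(NULL)
    kw <- kruskal_wallis(vg)
    ph <- pairwise_posthoc(vg)
    adj <- stats::setNames(ph$p_adj, paste0("p_", ph$group_a, "_", ph$group_b))
    tibble::tibble(feature = f, H = kw$H, df = kw$df, p = kw$p,
                   epsilon_sq = kw$epsilon_sq, !!!as.list(adj))
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$p), ]
}

#' Correlate an in-game feature with the neuropsychological instruments
#'
#' @param features feature matrix.
#' @param cohort cohort table carrying `mmse`, `moca`, `tmt_a`, `tmt_b`.
#' @param feature in-game feature to correlate (default the total-period
#'   mean of the high-resolution monitoring games).
#' @param tests instrument columns to correlate against.
#' @return tibble: `x_name`, `y_name`, `r`, `p`, `n`.
#' @export
correlate_with_tests <- function(features, cohort, feature = "HRMGMeanTotal",
                                 tests = c("mmse", "moca", "tmt_a", "tmt_b")) {
  merged <- dplyr::inner_join(features[, c("participant_id", feature)],
                              cohort[, c("id", tests)],
                              by = c(participant_id = "id"))
  dplyr::bind_rows(lapply(tests, function(t) {
    pc <- pearson_corr(merged[[feature]], merged[[t]])
    tibble::tibble(x_name = feature, y_name = t, r = pc$r, p = pc$p, n = pc$n)
  }))
}
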
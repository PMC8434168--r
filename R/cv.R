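#' Stratified fold assignment
#'
#' Shuffles indices within each class (seeded) and deals them round-robin
#' across `k` folds, so fold class proportions match the sample as closely
#' as integer counts allow.
#'
#' @param y class factor.
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  fold <- integer(length(y))
  with_seed(seed, {
    offset <- 0L
    for (cl in levels(as.factor(y))) {
      idx <- sample(which(y == cl))
      fold[idx] <- ((seq_along(idx) + offset - 1L) %% k) + 1L
      offset <- offset + length(idx)  # continue dealing across classes
    }
  })
  fold
}

impute_train_means <- function(train, test) {
  mu <- colMeans(train, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  fill <- function(M) {
    for (j in seq_len(ncol(M))) {
      bad <- !is.finite(M[, j])
      if (any(bad)) M[bad, j] <- mu[j]
    }
    M
  }
  list(train = fill(train), test = fill(test))
}

#' Stratified k-fold cross-validation of the perceptron classifier
#'
#' Runs stratified k-fold cross-validation with fold-internal mean
#' imputation and (optionally) fold-internal CFS/best-first feature
#' selection, pools the out-of-fold predictions into a confusion matrix
#' and computes the per-class report: TP rate, FP rate, sensitivity,
#' specificity and one-vs-rest ROC area from the pooled out-of-fold
#' probabilities.
#'
#' Selection modes: `"none"` uses all features; `"once"` selects on the
#' full data before cross-validation (the single ranked feature set
#' protocol, optimistic because selection sees the test folds); `"nested"`
#' re-selects inside each training fold (leakage-free).
#'
#' @param X predictor data frame / matrix (may contain NAs).
#' @param y class factor.
#' @param k folds.
#' @param seed RNG seed (folds, network initialization).
#' @param selection `"none"`, `"once"` or `"nested"`.
#' @param stale_limit best-first stopping patience.
#' @param bins discretization bins for the association provider.
#' @param ... passed to [mlp_train()] (`hidden`, `lr`, `momentum`,
#'   `epochs`, ...).
#' @return object of class `classifier_report`: `confusion` (rows = true
#'   class), `per_class` tibble, `overall_accuracy` (percent),
#'   `selected_features` (per fold, or the single set), `probs`
#'   (out-of-fold probability matrix), `y`, `fold`.
#' @export
cross_validate <- function(X, y, k = 10L, seed = 1L,
                           selection = c("none", "once", "nested"),
                           stale_limit = 5L, bins = 5L, ...) {
  selection <- match.arg(selection)
  X <- as.data.frame(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  fold <- stratified_folds(y, k, seed)
  selected_features <- list()

  if (selection == "once") {
    imp <- impute_train_means(as.matrix(X), as.matrix(X))
    sel <- best_first_select(association_matrix(as.data.frame(imp$train), y, bins),
                             stale_limit)
    X <- X[, sel$selected, drop = FALSE]
    selected_features <- list(all_data = sel$selected)
  }

  probs <- matrix(NA_real_, nrow(X), nlevels(y), dimnames = list(NULL, levels(y)))
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- !tr
    Xtr <- as.matrix(X[tr, , drop = FALSE])
    Xte <- as.matrix(X[te, , drop = FALSE])
    imp <- impute_train_means(Xtr, Xte)
    Xtr <- imp$train; Xte <- imp$test
    if (selection == "nested") {
      sel <- best_first_select(
        association_matrix(as.data.frame(Xtr), y[tr], bins), stale_limit)
      keep <- if (length(sel$selected) > 0) sel$selected else colnames(Xtr)
      selected_features[[paste0("fold_", f)]] <- sel$selected
      Xtr <- Xtr[, keep, drop = FALSE]
      Xte <- Xte[, keep, drop = FALSE]
    }
    fit <- mlp_train(Xtr, y[tr], seed = seed + f, ...)
    P <- predict(fit, Xte, type = "prob")
    full <- matrix(0, sum(te), nlevels(y), dimnames = list(NULL, levels(y)))
    full[, colnames(P)] <- P
    probs[te, ] <- full
  }
  classifier_report(probs, y, fold, selected_features)
}

#' Assemble a classifier report from pooled out-of-fold probabilities
#'
#' @param probs matrix of class probabilities (columns named by class).
#' @param y true class factor.
#' @param fold fold assignment (kept for provenance).
#' @param selected_features list of selected feature sets.
#' @return `classifier_report` object; see [cross_validate()].
#' @export
classifier_report <- function(probs, y, fold = NULL, selected_features = list()) {
  lev <- levels(y)
  pred <- factor(lev[max.col(probs, ties.method = "first")], levels = lev)
  confusion <- table(true = y, predicted = pred)
  n <- length(y)
  per_class <- dplyr::bind_rows(lapply(lev, function(cl) {
    tp <- sum(y == cl & pred == cl)
    fn <- sum(y == cl & pred != cl)
    fp <- sum(y != cl & pred == cl)
    tn <- sum(y != cl & pred != cl)
    roc <- roc_curve(probs[, cl], y == cl, direction = "higher_is_positive")
    tibble::tibble(class = cl,
                   tp_rate = tp / (tp + fn),
                   fp_rate = fp / (fp + tn),
                   sensitivity = tp / (tp + fn),
                   specificity = tn / (tn + fp),
                   roc_area = roc$auc)
  }))
  structure(list(confusion = confusion, per_class = per_class,
                 overall_accuracy = 100 * sum(diag(confusion)) / n,
                 selected_features = selected_features,
                 probs = probs, y = y, fold = fold),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Stratified cross-validation report\n")
  cat(sprintf("Overall accuracy: %.2f%%\n", x$overall_accuracy))
  print(x$confusion)
  df <- as.data.frame(x$per_class)
  df[-1] <- lapply(df[-1], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
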
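#' Equal-frequency discretization
#'
#' Bins a continuous variable into (up to) `bins` equal-frequency bins by
#' sample quantiles; duplicate breakpoints collapse, so heavily tied
#' variables may yield fewer bins. Deterministic.
#'
#' @param x numeric vector (NAs kept as NA).
#' @param bins target number of bins.
#' @return integer vector of bin indices.
#' @export
discretize_ef <- function(x, bins = 5L) {
  ok <- is.finite(x)
  br <- unique(stats::quantile(x[ok], probs = seq(0, 1, length.out = bins + 1),
                               type = 7, names = FALSE))
  if (length(br) < 2) return(ifelse(ok, 1L, NA_integer_))
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(cut(x[ok], breaks = br, include.lowest = TRUE))
  out
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Symmetric uncertainty between two discrete variables
#'
#' `2 * I(X;Y) / (H(X) + H(Y))`, in \[0,1\]; 0 for independent variables,
#' 1 for deterministically related ones. Pairwise-complete observations.
#'
#' @param x,y discrete vectors (factors or integer codes).
#' @return symmetric uncertainty in \[0,1\].
#' @export
symmetric_uncertainty <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n == 0) return(0)
  hx <- entropy_nats(table(x) / n)
  hy <- entropy_nats(table(y) / n)
  if (hx + hy == 0) return(0)
  hxy <- entropy_nats(table(x, y) / n)
  su <- 2 * (hx + hy - hxy) / (hx + hy)
  clip(su, 0, 1)
}

#' Feature-class and feature-feature association structure
#'
#' Discretizes each feature into equal-frequency bins (class kept
#' categorical) and computes symmetric uncertainties: feature-class and
#' all feature pairs. This is the association provider consumed by
#' [cfs_merit()] and [best_first_select()].
#'
#' @param X data frame / tibble of numeric features.
#' @param y class factor.
#' @param bins discretization bins.
#' @return list: `cf` (named vector), `ff` (symmetric matrix, unit
#'   diagonal).
#' @export
association_matrix <- function(X, y, bins = 5L) {
  feats <- names(X)
  D <- lapply(X, discretize_ef, bins = bins)
  cf <- vapply(D, symmetric_uncertainty, numeric(1), y = y)
  p <- length(feats)
  ff <- diag(1, p)
  dimnames(ff) <- list(feats, feats)
  if (p > 1)
    for (i in 1:(p - 1)) for (j in (i + 1):p)
      ff[i, j] <- ff[j, i] <- symmetric_uncertainty(D[[i]], D[[j]])
  list(cf = cf, ff = ff)
}

#' CFS merit of a feature subset
#'
#' Correlation-based feature selection heuristic
#' `k * rcf / sqrt(k + k (k - 1) * rff)` where `rcf` is the mean
#' feature-class association and `rff` the mean pairwise feature-feature
#' association of the subset: subsets highly associated with the class but
#' mutually non-redundant score highest. The empty subset has merit 0 by
#' convention.
#'
#' @param subset character vector of feature names.
#' @param assoc association provider from [association_matrix()] (or any
#'   list with `cf` and `ff` of matching names).
#' @return non-negative merit.
#' @export
cfs_merit <- function(subset, assoc) {
  k <- length(subset)
  if (k == 0) return(0)
  rcf <- mean(assoc$cf[subset])
  rff <- if (k == 1) 0 else mean(assoc$ff[subset, subset][lower.tri(diag(k))])
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Best-first forward search over feature subsets
#'
#' Greedy hill climbing with backtracking: starting from the empty set, it
#' keeps a priority queue of evaluated subsets, repeatedly expands the
#' best unexpanded one by all single-feature additions, and stops after
#' `stale_limit` consecutive expansions that fail to improve the best
#' merit seen. Ties are broken by lexicographic subset key, so the search
#' is deterministic.
#'
#' @param assoc association provider ([association_matrix()]).
#' @param stale_limit consecutive non-improving expansions tolerated.
#' @return list of class `selection_result`: `selected` (feature names in
#'   order of addition), `merit`, `n_evaluated`.
#' @export
best_first_select <- function(assoc, stale_limit = 5L) {
  feats <- names(assoc$cf)
  if (length(feats) == 0) stop("no candidate features", call. = FALSE)
  key_of <- function(s) paste(sort(s), collapse = "|")
  open_keys <- character(); open_merit <- numeric()
  subsets <- list(); order_of <- list()
  evaluated <- character()
  push <- function(s, ord) {
    k <- key_of(s)
    if (k %in% evaluated) return(NULL)
    evaluated <<- c(evaluated, k)
    m <- cfs_merit(s, assoc)
    open_keys <<- c(open_keys, k); open_merit <<- c(open_merit, m)
    subsets[[k]] <<- s; order_of[[k]] <<- ord
    m
  }
  push(character(0), character(0))
  best_key <- ""; best_merit <- 0
  stale <- 0L
  eps <- 1e-12
  while (length(open_keys) > 0 && stale < stale_limit) {
    i <- order(-open_merit, open_keys)[1]
    k <- open_keys[i]; s <- subsets[[k]]
    open_keys <- open_keys[-i]; open_merit <- open_merit[-i]
    improved <- FALSE
    for (f in sort(setdiff(feats, s))) {
      m <- push(c(s, f), c(order_of[[k]], f))
      if (!is.null(m) && m > best_merit + eps) {
        best_merit <- m; best_key <- key_of(c(s, f)); improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  selected <- if (best_key == "") character(0) else order_of[[best_key]]
  structure(list(selected = selected, merit = best_merit,
                 n_evaluated = length(evaluated)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Best-first CFS selection: merit", format(x$merit, digits = 4),
      "over", x$n_evaluated, "evaluated subsets\n")
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
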
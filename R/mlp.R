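#' Train a one-hidden-layer perceptron classifier
#'
#' Feedforward network with sigmoid hidden and output units and one-hot
#' targets, trained by per-sample stochastic gradient descent on squared
#' error with momentum. Defaults mirror the classic WEKA-style
#' configuration: hidden units = ceiling((features + classes) / 2),
#' learning rate 0.3, momentum 0.2, 500 epochs, inputs z-standardized on
#' the training data. Training is deterministic given `seed` (weight
#' initialization and epoch shuffling).
#'
#' @param X numeric matrix / data frame of predictors (no missing values).
#' @param y class factor (>= 2 classes present).
#' @param hidden hidden-layer size; `NULL` for the default rule.
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param epochs training epochs (passes over the shuffled data).
#' @param init_scale weights initialized uniformly on
#'   `[-init_scale, init_scale]`.
#' @param seed RNG seed for initialization and shuffling.
#' @return object of class `exerscreen_mlp`.
#' @export
mlp_train <- function(X, y, hidden = NULL, lr = 0.3, momentum = 0.2,
                      epochs = 500L, init_scale = 0.5, seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training data contains a single class", call. = FALSE)
  if (any(!is.finite(X))) stop("missing values in predictors; impute first", call. = FALSE)
  d <- ncol(X); k <- nlevels(y); n <- nrow(X)
  if (is.null(hidden)) hidden <- ceiling((d + k) / 2)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Y <- diag(k)[as.integer(y), , drop = FALSE]

  sig <- function(z) 1 / (1 + exp(-z))
  with_seed(seed, {
    W1 <- matrix(stats::runif(hidden * d, -init_scale, init_scale), hidden, d)
    b1 <- stats::runif(hidden, -init_scale, init_scale)
    W2 <- matrix(stats::runif(k * hidden, -init_scale, init_scale), k, hidden)
    b2 <- stats::runif(k, -init_scale, init_scale)
    vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        x <- Xs[i, ]
        h <- sig(W1 %*% x + b1)
        o <- sig(W2 %*% h + b2)
        do <- (o - Y[i, ]) * o * (1 - o)
        dh <- (t(W2) %*% do) * h * (1 - h)
        vW2 <- momentum * vW2 - lr * (do %*% t(h)); W2 <- W2 + vW2
        vb2 <- momentum * vb2 - lr * c(do);         b2 <- b2 + vb2
        vW1 <- momentum * vW1 - lr * (dh %*% t(x)); W1 <- W1 + vW1
        vb1 <- momentum * vb1 - lr * c(dh);         b1 <- b1 + vb1
      }
    }
    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                   center = ctr, scale = scl, levels = levels(y),
                   hidden = hidden),
              class = "exerscreen_mlp")
  })
}

#' Predict class probabilities or labels from a trained perceptron
#' @param object an `exerscreen_mlp` model.
#' @param newdata predictor matrix / data frame.
#' @param type `"prob"` for normalized class probabilities, `"class"` for
#'   the argmax label.
#' @param ... unused.
#' @export
predict.exerscreen_mlp <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  sig <- function(z) 1 / (1 + exp(-z))
  H <- sig(Xs %*% t(object$W1) + matrix(object$b1, nrow(Xs), length(object$b1), byrow = TRUE))
  O <- sig(H %*% t(object$W2) + matrix(object$b2, nrow(Xs), length(object$b2), byrow = TRUE))
  P <- O / rowSums(O)
  colnames(P) <- object$levels
  if (type == "prob") return(P)
  factor(object$levels[max.col(P, ties.method = "first")], levels = object$levels)
}
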
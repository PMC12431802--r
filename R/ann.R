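#' Initialize a single-hidden-layer feed-forward network
#'
#' Architecture: k input nodes (one per signature gene score), `n_hidden`
#' logistic hidden units (default 5), and a single logistic output unit
#' whose activation is the probability of the case class. Weights are drawn
#' i.i.d. uniform(-0.5, 0.5) from the seeded RNG; biases start at 0.
#'
#' For a two-class problem the single-sigmoid output is functionally
#' equivalent to a two-node softmax output layer and yields the ROC score
#' directly.
#'
#' @param n_inputs Number of input features (signature genes), k.
#' @param n_hidden Hidden units (default 5).
#' @param seed RNG seed for the weight draw.
#' @return An `ann_model`: `W1` (n_hidden x k), `b1` (n_hidden), `W2`
#'   (1 x n_hidden), `b2` (scalar), `feature_names` (filled in by
#'   [ann_train()]), and a `meta` list.
#' @export
ann_init <- function(n_inputs, n_hidden = 5L, seed = 1L) {
  n_inputs <- as.integer(n_inputs)
  n_hidden <- as.integer(n_hidden)
  if (n_inputs < 1L || n_hidden < 1L)
    stop("n_inputs and n_hidden must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  structure(list(
    W1 = matrix(stats::runif(n_hidden * n_inputs, -0.5, 0.5),
                n_hidden, n_inputs),
    b1 = rep(0, n_hidden),
    W2 = matrix(stats::runif(n_hidden, -0.5, 0.5), 1L, n_hidden),
    b2 = 0,
    feature_names = NULL,
    meta = list(seed = as.integer(seed), trained = FALSE)),
    class = "ann_model")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass; X is samples x k. Returns hidden activations and output
# probabilities (needed for backprop).
ann_forward <- function(model, X) {
  A1 <- sigmoid(X %*% t(model$W1) +
                  matrix(model$b1, nrow(X), length(model$b1), byrow = TRUE))
  p <- as.vector(sigmoid(A1 %*% t(model$W2) + model$b2))
  list(A1 = A1, p = p)
}

# Loss and analytic gradients for one full batch. Binary cross-entropy
# (mean over samples) by default; sum-of-squared-errors available.
ann_loss_grad <- function(model, X, y, loss = c("cross_entropy", "sse")) {
  loss <- match.arg(loss)
  n <- nrow(X)
  fwd <- ann_forward(model, X)
  p <- fwd$p
  A1 <- fwd$A1
  if (loss == "cross_entropy") {
    eps <- 1e-12
    value <- -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
    delta_out <- (p - y) / n                     # d loss / d z_out
  } else {
    value <- mean((p - y)^2)
    delta_out <- 2 * (p - y) * p * (1 - p) / n
  }
  gW2 <- matrix(delta_out, 1L) %*% A1            # 1 x hidden
  gb2 <- sum(delta_out)
  delta_hid <- (delta_out %*% model$W2) * A1 * (1 - A1)  # n x hidden
  gW1 <- t(delta_hid) %*% X                      # hidden x k
  gb1 <- colSums(delta_hid)
  list(value = value, gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2)
}

#' Train the network by full-batch gradient descent
#'
#' Backpropagation with logistic activations throughout, minimizing binary
#' cross-entropy (default) or sum of squared errors. Training stops when the
#' loss decrease falls below `tol` or after `max_epochs`. Deterministic
#' given the initialized model and the data.
#'
#' @param model An [ann_init()] model (its input width must match the score
#'   matrix).
#' @param scores A `gene_score_matrix` from [score_matrix()], or a plain
#'   numeric samples-x-features matrix with column names.
#' @param labels Binary 0/1 vector (1 = case), one per score row.
#' @param lr Learning rate (default 0.1).
#' @param max_epochs Default 10000.
#' @param tol Convergence tolerance on the loss decrease (default 1e-6).
#' @param loss `"cross_entropy"` (default) or `"sse"`.
#' @return The trained `ann_model` with `feature_names` set and `meta`
#'   recording epochs run, final loss, learning rate, and a convergence
#'   flag.
#' @export
ann_train <- function(model, scores, labels, lr = 0.1, max_epochs = 10000L,
                      tol = 1e-6, loss = c("cross_entropy", "sse")) {
  stopifnot(inherits(model, "ann_model"))
  loss <- match.arg(loss)
  X <- score_input(scores)
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1)))
    stop("labels must be binary 0/1", call. = FALSE)
  if (nrow(X) != length(y))
    stop("score matrix has ", nrow(X), " rows but ", length(y), " labels",
         call. = FALSE)
  if (ncol(X) != ncol(model$W1))
    stop("model expects ", ncol(model$W1), " input features but the score ",
         "matrix has ", ncol(X), call. = FALSE)

  prev <- Inf
  epochs <- 0L
  converged <- FALSE
  final <- NA_real_
  for (epoch in seq_len(max_epochs)) {
    g <- ann_loss_grad(model, X, y, loss)
    if (!is.finite(g$value))
      stop("training diverged (non-finite loss) at epoch ", epoch,
           "; lower the learning rate", call. = FALSE)
    model$W1 <- model$W1 - lr * g$gW1
    model$b1 <- model$b1 - lr * g$gb1
    model$W2 <- model$W2 - lr * g$gW2
    model$b2 <- model$b2 - lr * g$gb2
    epochs <- epoch
    final <- g$value
    if (prev - g$value < tol && epoch > 1L) {
      converged <- TRUE
      break
    }
    prev <- g$value
  }
  dimnames(model$W1) <- NULL
  dimnames(model$W2) <- NULL
  names(model$b1) <- NULL
  model$feature_names <- colnames(X)
  model$meta <- utils::modifyList(model$meta, list(
    trained = TRUE, epochs = epochs, final_loss = final, lr = lr,
    tol = tol, loss = loss, converged = converged))
  model
}

# Accept either a gene_score_matrix or a bare matrix as ANN input.
score_input <- function(scores) {
  if (inherits(scores, "gene_score_matrix")) scores$scores else {
    stopifnot(is.matrix(scores))
    scores
  }
}

#' Predict case probabilities
#'
#' @param object A trained `ann_model`.
#' @param scores Score matrix whose columns match the model's features. If
#'   the column set matches but the order differs, columns are reordered; a
#'   differing set is a feature-mismatch error listing the symmetric
#'   difference.
#' @param ... Unused.
#' @return Named numeric vector of case probabilities in (0, 1); the
#'   predicted class is case where probability > 0.5.
#' @export
predict.ann_model <- function(object, scores, ...) {
  X <- score_input(scores)
  feats <- object$feature_names
  if (!is.null(feats)) {
    if (!setequal(colnames(X), feats)) {
      diff <- c(setdiff(feats, colnames(X)), setdiff(colnames(X), feats))
      stop("feature mismatch between model and score matrix: ",
           paste(diff, collapse = ", "), call. = FALSE)
    }
    X <- X[, feats, drop = FALSE]
  } else if (ncol(X) != ncol(object$W1)) {
    stop("model expects ", ncol(object$W1), " features but got ", ncol(X),
         call. = FALSE)
  }
  p <- ann_forward(object, X)$p
  stats::setNames(p, rownames(X))
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("ann_model: %d inputs -> %d hidden -> 1 logistic output%s\n",
              ncol(x$W1), nrow(x$W1),
              if (isTRUE(x$meta$trained))
                sprintf(" (trained, %d epochs, loss %.4g)",
                        x$meta$epochs, x$meta$final_loss) else " (untrained)"))
  invisible(x)
}
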
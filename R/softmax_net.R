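# Softmax output layer: encoding, probabilities, cost, gradients, training.

#' One-hot encode class labels
#'
#' @param labels integer class indices in `1..k`.
#' @param k number of classes.
#' @return n x k binary matrix with a single 1 per row (row `i` has the 1 in
#'   column `labels[i]`).
#' @export
one_hot_encode <- function(labels, k) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 1L) || any(labels > k))
    stop_hep2(sprintf("labels must be integers in 1..%d", k),
              "hep2hos_bad_labels")
  Y <- matrix(0, length(labels), k)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

#' Row-wise softmax
#'
#' `softmax(z)_j = exp(z_j) / sum_l exp(z_l)` per row, computed with
#' max-subtraction so arbitrarily large net inputs stay finite. Rows sum to 1.
#'
#' @param Z n x k matrix of net inputs (a vector is treated as one row).
#' @return n x k matrix of probabilities in (0, 1).
#' @export
softmax <- function(Z) {
  if (!is.matrix(Z)) Z <- matrix(Z, nrow = 1)
  stopifnot(all(is.finite(Z)))
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Net input XW + b.
.net_input <- function(X, W, b) {
  if (ncol(X) != nrow(W))
    stop_hep2(sprintf("descriptor dimension %d does not match model (%d)",
                      ncol(X), nrow(W)), "hep2hos_dim_mismatch")
  sweep(X %*% W, 2, b, "+")
}

#' Regularised cross-entropy cost
#'
#' Mean cross-entropy over samples plus the L2 penalty `lambda/2 * sum(W^2)`
#' (biases are not penalised). Probabilities at target positions are clamped
#' at `1e-15` before the log.
#'
#' @param Y n x k one-hot target matrix.
#' @param O n x k probability matrix.
#' @param W weight matrix (only needed when `lambda > 0`).
#' @param lambda L2 regularisation strength.
#' @return scalar cost `J`.
#' @export
softmax_cost <- function(Y, O, W = NULL, lambda = 0) {
  stopifnot(all(dim(Y) == dim(O)))
  ce <- -sum(Y * log(pmax(O, 1e-15))) / nrow(Y)
  pen <- if (lambda > 0) lambda / 2 * sum(W^2) else 0
  ce + pen
}

#' Analytic gradients of the regularised cross-entropy
#'
#' `gradW = X'(O - Y)/n + lambda W` and `gradB = colMeans(O - Y)`.
#'
#' @param X n x m descriptor matrix.
#' @param Y n x k one-hot targets.
#' @param O n x k softmax probabilities.
#' @param W m x k weight matrix.
#' @param lambda L2 strength.
#' @return list with `gradW` (m x k) and `gradB` (length k).
#' @export
softmax_gradients <- function(X, Y, O, W, lambda = 0) {
  if (nrow(X) != nrow(Y) || any(dim(Y) != dim(O)) ||
      ncol(X) != nrow(W) || ncol(Y) != ncol(W))
    stop_hep2("shape mismatch among X, Y, O, W", "hep2hos_dim_mismatch")
  R <- O - Y
  list(gradW = crossprod(X, R) / nrow(X) + lambda * W,
       gradB = colSums(R) / nrow(X))
}

#' Train a softmax classifier by full-batch gradient descent
#'
#' Minimises the mean cross-entropy with L2 penalty over `iterations` steps
#' of plain full-batch gradient descent. Weights start from a seeded uniform
#' draw in \[0, 0.1\] (`init = "uniform"`); `init = "fixed"` instead uses the
#' deterministic reference initialisation for `k = 6`: every weight row
#' `c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)` and bias
#' `c(0.01, 0.1, 0.1, 0.1, 0.1, 0.1)`.
#'
#' @param X n x m descriptor matrix.
#' @param labels integer class indices in `1..k`.
#' @param k number of classes (default: `max(labels)`).
#' @param eta learning rate in (0, 1\].
#' @param iterations gradient steps.
#' @param lambda L2 regularisation strength.
#' @param seed seed for the weight initialisation.
#' @param init `"uniform"` or `"fixed"` (see above).
#' @return list with `W`, `b`, `trace` (cost per iteration, evaluated before
#'   each update), `eta`, `lambda`, `iterations`, `k`.
#' @export
softmax_fit <- function(X, labels, k = max(labels), eta = 0.01,
                        iterations = 500L, lambda = 0.01, seed = 1L,
                        init = c("uniform", "fixed")) {
  init <- match.arg(init)
  X <- as.matrix(X)
  labels <- as.integer(labels)
  stopifnot(eta > 0, eta <= 1, lambda >= 0, iterations >= 1)
  if (nrow(X) < k)
    stop_hep2("need at least as many samples as classes", "hep2hos_bad_data")
  if (length(unique(labels)) < 2)
    stop_hep2("labels must cover at least 2 classes", "hep2hos_bad_data")
  Y <- one_hot_encode(labels, k)
  m <- ncol(X)

  if (init == "fixed") {
    if (k != 6)
      stop_hep2("the fixed reference initialisation is defined for k = 6",
                "hep2hos_bad_init")
    W <- matrix(rep(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), each = m), m, k)
    b <- c(0.01, 0.1, 0.1, 0.1, 0.1, 0.1)
  } else {
    W <- with_seed(seed, matrix(runif(m * k, 0, 0.1), m, k))
    b <- numeric(k)
  }

  trace <- numeric(iterations)
  for (it in seq_len(iterations)) {
    O <- softmax(.net_input(X, W, b))
    J <- softmax_cost(Y, O, W, lambda)
    if (!is.finite(J))
      stop_hep2(sprintf("non-finite cost at iteration %d (eta too large?)", it),
                "hep2hos_diverged")
    trace[it] <- J
    g <- softmax_gradients(X, Y, O, W, lambda)
    W <- W - eta * g$gradW
    b <- b - eta * g$gradB
  }

  list(W = W, b = b, trace = trace, eta = eta, lambda = lambda,
       iterations = as.integer(iterations), k = as.integer(k))
}

#' Predict classes from a trained softmax layer
#'
#' Argmax of `softmax(XW + b)`; ties break toward the lowest class index.
#'
#' @param X n x m descriptor matrix.
#' @param model a [softmax_fit()] result (or any list with `W` and `b`).
#' @return list with `labels` (integer predictions) and `prob` (n x k
#'   probability matrix).
#' @export
softmax_predict <- function(X, model) {
  O <- softmax(.net_input(as.matrix(X), model$W, model$b))
  list(labels = apply(O, 1, which.max), prob = O)
}
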
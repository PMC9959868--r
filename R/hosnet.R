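# The adapted network: fixed L-moment hidden layer + trained softmax output.

#' Fit the L-moment softmax network
#'
#' The core classifier: each image's higher-order-spectra feature vector is
#' summarised by the fixed L-moment hidden layer ([lmoment_descriptor()]),
#' descriptor columns are optionally standardised, and a multi-class softmax
#' output layer is trained by full-batch gradient descent on the regularised
#' cross-entropy ([softmax_fit()]). Only the softmax weights are learned; the
#' L-moment layer is a fixed transform.
#'
#' @param x feature matrix, rows = images (e.g. from
#'   [extract_features_batch()]); with `grouping = "none"`, `x` is used
#'   directly as the descriptor matrix.
#' @param labels class labels: a factor/character vector (levels recorded in
#'   the fit) or integer indices in `1..k`.
#' @param grouping descriptor grouping passed to [lmoment_descriptor()], or
#'   `"none"`.
#' @param n_angles,block_size grouping parameters, see [lmoment_descriptor()].
#' @param standardize standardise descriptor columns to zero mean and unit
#'   variance before training (constant columns are left unscaled); the same
#'   transform is applied at prediction time.
#' @param eta,iterations,lambda,seed,init training hyperparameters, see
#'   [softmax_fit()].
#' @param classes optional explicit class-name vector (defaults to the factor
#'   levels of `labels`, or [hep2_classes] for integer labels of 6 classes).
#' @return an object of class `hosnet` with `print`, `summary`, `coef`,
#'   `predict`, `plot`, `fitted`, `residuals` and `simulate` methods.
#' @seealso [run_pipeline()] for the full image-to-report pipeline.
#' @export
hosnet <- function(x, labels, grouping = c("per_angle", "per_slope", "global",
                                           "fixed_blocks", "none"),
                   n_angles = NULL, block_size = NULL, standardize = TRUE,
                   eta = 0.01, iterations = 500L, lambda = 0.01, seed = 1L,
                   init = c("uniform", "fixed"), classes = NULL) {
  grouping <- match.arg(grouping)
  init <- match.arg(init)

  if (is.factor(labels) || is.character(labels)) {
    f <- if (is.factor(labels)) labels else
      factor(labels, levels = if (all(labels %in% hep2_classes)) hep2_classes
             else sort(unique(labels)))
    classes <- classes %||% levels(f)
    y <- as.integer(f)
  } else {
    y <- as.integer(labels)
    classes <- classes %||%
      (if (max(y) == length(hep2_classes)) hep2_classes else
        as.character(seq_len(max(y))))
  }
  k <- length(classes)

  D <- if (grouping == "none") as.matrix(x) else
    lmoment_descriptor(x, grouping = grouping, block_size = block_size,
                       n_angles = n_angles %||% attr(x, "n_angles"))
  if (!is.matrix(D)) D <- matrix(D, nrow = 1)

  center <- scale <- NULL
  if (standardize) {
    center <- colMeans(D)
    scale <- apply(D, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
    D <- sweep(sweep(D, 2, center), 2, scale, "/")
  }

  fit <- softmax_fit(D, y, k = k, eta = eta, iterations = iterations,
                     lambda = lambda, seed = seed, init = init)
  structure(
    c(fit, list(classes = classes, grouping = grouping,
                n_angles = n_angles %||% attr(x, "n_angles"),
                block_size = block_size, standardize = standardize,
                center = center, scale = scale, descriptors = D, y = y,
                feature_config = attr(x, "config"))),
    class = "hosnet")
}

# Map new inputs (features or descriptors) into the model's descriptor space.
.hosnet_descriptor <- function(object, newdata) {
  x <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  D <- if (object$grouping == "none") x else
    lmoment_descriptor(x, grouping = object$grouping,
                       block_size = object$block_size,
                       n_angles = object$n_angles %||% attr(x, "n_angles"))
  if (!is.matrix(D)) D <- matrix(D, nrow = 1)
  if (isTRUE(object$standardize) && !is.null(object$center))
    D <- sweep(sweep(D, 2, object$center), 2, object$scale, "/")
  D
}

#' @describeIn hosnet predict classes (`type = "class"`, the default, returns
#'   a factor with the fit's class levels) or class probabilities
#'   (`type = "prob"`). Ties break toward the lowest class index.
#' @param object,newdata,type,... method arguments; `newdata` defaults to the
#'   training data.
#' @export
predict.hosnet <- function(object, newdata = NULL, type = c("class", "prob"),
                           ...) {
  type <- match.arg(type)
  D <- if (is.null(newdata)) object$descriptors else
    .hosnet_descriptor(object, newdata)
  pr <- softmax_predict(D, object)
  if (type == "prob") {
    colnames(pr$prob) <- object$classes
    return(pr$prob)
  }
  factor(object$classes[pr$labels], levels = object$classes)
}

#' @export
print.hosnet <- function(x, ...) {
  cat("L-moment softmax network\n")
  cat(sprintf("  classes:    %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  descriptor: %d units (grouping: %s%s)\n", nrow(x$W),
              x$grouping,
              if (isTRUE(x$standardize)) ", standardised" else ""))
  cat(sprintf("  training:   eta = %g, lambda = %g, %d iterations\n",
              x$eta, x$lambda, x$iterations))
  cat(sprintf("  final cost: %.6f\n", x$trace[length(x$trace)]))
  invisible(x)
}

#' @export
summary.hosnet <- function(object, ...) {
  pred <- softmax_predict(object$descriptors, object)$labels
  out <- list(classes = object$classes, m = nrow(object$W),
              n = nrow(object$descriptors),
              eta = object$eta, lambda = object$lambda,
              iterations = object$iterations,
              initial_cost = object$trace[1],
              final_cost = object$trace[length(object$trace)],
              train_accuracy = mean(pred == object$y))
  class(out) <- "summary.hosnet"
  out
}

#' @export
print.summary.hosnet <- function(x, ...) {
  cat("L-moment softmax network\n")
  cat(sprintf("  %d training samples, %d descriptor units, %d classes\n",
              x$n, x$m, length(x$classes)))
  cat(sprintf("  eta = %g, lambda = %g, %d iterations\n",
              x$eta, x$lambda, x$iterations))
  cat(sprintf("  cost: %.6f -> %.6f\n", x$initial_cost, x$final_cost))
  cat(sprintf("  training accuracy: %.4f\n", x$train_accuracy))
  invisible(x)
}

#' @export
coef.hosnet <- function(object, ...) {
  out <- rbind(object$b, object$W)
  rownames(out) <- c("(bias)", paste0("d", seq_len(nrow(object$W))))
  colnames(out) <- object$classes
  out
}

#' @export
fitted.hosnet <- function(object, ...) {
  O <- softmax_predict(object$descriptors, object)$prob
  colnames(O) <- object$classes
  O
}

#' @export
residuals.hosnet <- function(object, ...) {
  one_hot_encode(object$y, length(object$classes)) - fitted(object)
}

#' @export
plot.hosnet <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "l",
                 xlab = "iteration", ylab = "cross-entropy cost",
                 main = "Training cost", ...)
  invisible(x)
}

#' @export
simulate.hosnet <- function(object, nsim = 1, seed = NULL, ...) {
  P <- fitted(object)
  sims <- with_seed(seed, replicate(nsim, {
    idx <- apply(P, 1, function(p) sample.int(length(p), 1, prob = p))
    factor(object$classes[idx], levels = object$classes)
  }, simplify = FALSE))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
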
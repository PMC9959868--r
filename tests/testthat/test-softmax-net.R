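test_that("one-hot encoding places single ones at the label positions", {
  expect_equal(one_hot_encode(1, 6)[1, ], c(1, 0, 0, 0, 0, 0))
  expect_equal(one_hot_encode(6, 6)[1, ], c(0, 0, 0, 0, 0, 1))
  Y <- one_hot_encode(c(2, 2, 5), 6)
  expect_equal(colSums(Y), c(0, 2, 0, 0, 1, 0))
  expect_equal(rowSums(Y), rep(1, 3))
  expect_error(one_hot_encode(7, 6), class = "hep2hos_bad_labels")
  expect_error(one_hot_encode(0, 6), class = "hep2hos_bad_labels")
})

test_that("softmax satisfies its closed forms and contracts", {
  expect_equal(softmax(rep(0, 6))[1, ], rep(1 / 6, 6))
  expect_equal(softmax(c(log(2), 0))[1, ], c(2 / 3, 1 / 3))
  # shift invariance
  set.seed(11)
  Z <- matrix(rnorm(40), 8, 5)
  expect_equal(softmax(Z), softmax(Z + 100), tolerance = 1e-12)
  # row sums and range, including extreme inputs
  O <- softmax(matrix(rnorm(60, sd = 200), 10, 6))
  expect_equal(rowSums(O), rep(1, 10), tolerance = 1e-12)
  expect_true(all(O >= 0 & O <= 1))
})

test_that("cost matches closed forms", {
  Y <- one_hot_encode(c(1, 3, 6), 6)
  expect_equal(softmax_cost(Y, Y), 0)
  U <- matrix(1 / 6, 3, 6)
  expect_equal(softmax_cost(Y, U), log(6))
  # zero weights contribute no penalty; nonzero lambda with W adds lam/2*||W||^2
  W <- matrix(2, 4, 6)
  expect_equal(softmax_cost(Y, U, W = W * 0, lambda = 0.5), log(6))
  expect_equal(softmax_cost(Y, U, W = W, lambda = 0.5),
               log(6) + 0.5 / 2 * sum(W^2))
})

test_that("analytic gradients match central finite differences", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(3:8, 1); m <- sample(2:5, 1); k <- sample(2:5, 1)
    X <- matrix(rnorm(n * m), n, m)
    y <- sample(k, n, replace = TRUE)
    Y <- one_hot_encode(y, k)
    W <- matrix(rnorm(m * k, sd = 0.5), m, k)
    b <- rnorm(k, sd = 0.5)
    lam <- sample(c(0, 0.01, 0.3), 1)
    O <- softmax(sweep(X %*% W, 2, b, "+"))
    g <- softmax_gradients(X, Y, O, W, lam)
    fd <- numeric_gradients(X, Y, W, b, lam)
    expect_equal(g$gradW, fd$gradW, tolerance = 1e-6)
    expect_equal(g$gradB, fd$gradB, tolerance = 1e-6)
  }
})

test_that("zero-residual gradients reduce to the penalty term", {
  X <- matrix(rnorm(12), 4, 3)
  Y <- one_hot_encode(c(1, 2, 1, 2), 2)
  W <- matrix(0.3, 3, 2)
  g <- softmax_gradients(X, Y, Y, W, lambda = 0.05)
  expect_equal(g$gradW, 0.05 * W)
  expect_equal(g$gradB, c(0, 0))
})

test_that("training on separable blobs reaches high accuracy deterministically", {
  blobs <- make_blobs(20, seed = 5)
  f1 <- softmax_fit(blobs$X, blobs$y, eta = 0.01, iterations = 500,
                    lambda = 0.01, seed = 3)
  acc <- mean(softmax_predict(blobs$X, f1)$labels == blobs$y)
  expect_gte(acc, 0.95)
  # bit-identical re-run
  f2 <- softmax_fit(blobs$X, blobs$y, eta = 0.01, iterations = 500,
                    lambda = 0.01, seed = 3)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$b, f2$b)
})

test_that("the cost trace is monotone non-increasing at a small step size", {
  blobs <- make_blobs(10, seed = 2)
  f <- softmax_fit(blobs$X, blobs$y, eta = 0.001, iterations = 300,
                   lambda = 0, seed = 1)
  expect_true(all(diff(f$trace) <= 1e-12))
})

test_that("stronger regularisation shrinks the converged weights", {
  blobs <- make_blobs(15, seed = 8)
  norms <- sapply(c(0, 0.01, 0.1, 1), function(lam)
    sum(softmax_fit(blobs$X, blobs$y, eta = 0.05, iterations = 400,
                    lambda = lam, seed = 4)$W^2))
  expect_true(all(diff(norms) <= 0))
})

test_that("prediction ties break toward the lowest class index", {
  model <- list(W = matrix(0, 3, 6), b = rep(0, 6))
  p <- softmax_predict(matrix(rnorm(6), 2, 3), model)
  expect_equal(p$labels, c(1, 1))
  expect_equal(p$prob[1, ], rep(1 / 6, 6))
  # a dominant bias wins everywhere
  model$b <- c(10, 0, 0, 0, 0, 0)
  p2 <- softmax_predict(matrix(rnorm(6), 2, 3), model)
  expect_equal(p2$labels, c(1, 1))
  expect_equal(p2$prob[1, 1], exp(10) / (exp(10) + 5), tolerance = 1e-12)
})

test_that("shape violations and degenerate inputs are rejected", {
  expect_error(softmax_predict(matrix(0, 2, 4), list(W = matrix(0, 3, 6),
                                                     b = rep(0, 6))),
               class = "hep2hos_dim_mismatch")
  expect_error(softmax_fit(matrix(rnorm(8), 4, 2), rep(1, 4)),
               class = "hep2hos_bad_data")
  # fixed reference initialisation is defined for k = 6 only
  expect_error(softmax_fit(matrix(rnorm(8), 4, 2), c(1, 2, 1, 2),
                           init = "fixed"),
               class = "hep2hos_bad_init")
})

test_that("the fixed reference initialisation is reproducible", {
  set.seed(31)
  X <- matrix(rnorm(36), 6, 6)
  # fit with 1 iteration: the trace records the cost at the documented start
  f <- softmax_fit(X, c(1, 2, 3, 4, 5, 6), k = 6, iterations = 1,
                   init = "fixed")
  W0 <- outer(rep(1, 6), seq(0.1, 0.6, by = 0.1))
  b0 <- c(0.01, 0.1, 0.1, 0.1, 0.1, 0.1)
  O0 <- softmax(sweep(X %*% W0, 2, b0, "+"))
  expect_equal(f$trace[1],
               softmax_cost(one_hot_encode(1:6, 6), O0, W0, 0.01))
})
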
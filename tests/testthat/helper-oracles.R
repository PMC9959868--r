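# Independent brute-force oracles used across the test files. These stay
# deliberately naive: loops and first-principles definitions, no reuse of the
# package's own computational paths.

# Count connected bright components of a binary matrix by literal flood fill
# (8-connectivity, explicit stack).
flood_fill_components <- function(bin) {
  seen <- matrix(FALSE, nrow(bin), ncol(bin))
  comps <- 0L
  for (r0 in seq_len(nrow(bin))) for (c0 in seq_len(ncol(bin))) {
    if (!bin[r0, c0] || seen[r0, c0]) next
    comps <- comps + 1L
    stack <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nrow(bin) && c >= 1 && c <= ncol(bin) &&
            bin[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  comps
}

# Brute-force bispectral line integral: double loop over the full (j1, j2)
# frequency grid, restricted to the line k2 = a*k1 by triangular interpolation
# weights, phases from first principles.
bispec_phases_bruteforce <- function(x, fft_len, n_slopes, center = TRUE) {
  if (center) x <- x - mean(x)
  F <- stats::fft(c(x, numeric(fft_len - length(x))))
  half <- fft_len / 2
  phases <- numeric(n_slopes)
  for (s in seq_len(n_slopes)) {
    a <- s / n_slopes
    acc <- 0 + 0i
    for (j1 in seq_len(floor(half / (1 + a) + 1e-12))) {
      for (j2 in 0:half) {
        w <- max(0, 1 - abs(a * j1 - j2))
        if (w > 0) acc <- acc + w * F[j1 + 1] * F[j2 + 1] * Conj(F[j1 + j2 + 1])
      }
    }
    phases[s] <- atan2(Im(acc), Re(acc))
  }
  phases
}

# Direct U-statistic definitions of the first four L-moments: averages of the
# order-statistic kernels over all 1-,2-,3-,4-element subsets.
lmoments_ustat <- function(x) {
  xs <- sort(x)  # combn preserves input order, so every subset is ascending
  l1 <- mean(xs)
  p2 <- utils::combn(xs, 2)
  l2 <- mean((p2[2, ] - p2[1, ]) / 2)
  p3 <- utils::combn(xs, 3)
  l3 <- mean((p3[3, ] - 2 * p3[2, ] + p3[1, ]) / 3)
  p4 <- utils::combn(xs, 4)
  l4 <- mean((p4[4, ] - 3 * p4[3, ] + 3 * p4[2, ] - p4[1, ]) / 4)
  c(L1 = l1, L2 = l2, L3 = l3, L4 = l4)
}

# Central finite differences of the regularised cross-entropy with respect to
# W and b.
numeric_gradients <- function(X, Y, W, b, lambda, eps = 1e-6) {
  costf <- function(W, b) {
    Z <- sweep(X %*% W, 2, b, "+")
    Z <- Z - apply(Z, 1, max)
    O <- exp(Z) / rowSums(exp(Z))
    -sum(Y * log(pmax(O, 1e-15))) / nrow(Y) + lambda / 2 * sum(W^2)
  }
  gW <- W * 0
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
    Wp <- W; Wm <- W
    Wp[i, j] <- W[i, j] + eps
    Wm[i, j] <- W[i, j] - eps
    gW[i, j] <- (costf(Wp, b) - costf(Wm, b)) / (2 * eps)
  }
  gB <- numeric(length(b))
  for (j in seq_along(b)) {
    bp <- b; bm <- b
    bp[j] <- b[j] + eps
    bm[j] <- b[j] - eps
    gB[j] <- (costf(W, bp) - costf(W, bm)) / (2 * eps)
  }
  list(gradW = gW, gradB = gB)
}

# Analytically rasterized disk mask and image.
make_disk <- function(size, radius, value = 0.9, cy = (size + 1) / 2,
                      cx = (size + 1) / 2) {
  yy <- matrix(seq_len(size), size, size)
  xx <- matrix(seq_len(size), size, size, byrow = TRUE)
  mask <- (yy - cy)^2 + (xx - cx)^2 <= radius^2
  list(image = mask * value, mask = mask)
}

dice_overlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Separable three-class Gaussian blobs in 2-D.
make_blobs <- function(n_per_class = 20, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  X <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(n_per_class, centers[k, 1], 0.8),
          rnorm(n_per_class, centers[k, 2], 0.8))))
  list(X = X, y = rep(1:3, each = n_per_class))
}
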
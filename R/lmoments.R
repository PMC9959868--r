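# Sample L-moments: the network's fixed first hidden layer.

#' Probability-weighted moments of a sample
#'
#' Unbiased estimators of the first four probability-weighted moments
#' `beta_0..beta_3` of the ascending sample `H_(1) <= ... <= H_(n)`:
#' \deqn{\beta_r = \frac{1}{n} \sum_{j=r+1}^{n} H_{(j)}
#'   \frac{(j-1)(j-2)\cdots(j-r)}{(n-1)(n-2)\cdots(n-r)}.}
#' The input is sorted internally if needed.
#'
#' @param sample numeric vector, length at least 4 (`beta_3` is undefined
#'   below that).
#' @return named numeric vector `c(beta0, beta1, beta2, beta3)`.
#' @export
#' @examples
#' pwm_betas(c(1, 2, 3, 4))  # 2.5, 5/3, 1.25, 1
pwm_betas <- function(sample) {
  x <- as.numeric(sample)
  n <- length(x)
  if (n < 4)
    stop_hep2("sample must have at least 4 values (beta3 undefined)",
              "hep2hos_short_sample")
  if (any(!is.finite(x)))
    stop_hep2("sample contains non-finite values", "hep2hos_bad_sample")
  x <- sort(x)
  j <- seq_len(n)
  b0 <- mean(x)
  b1 <- sum(x * (j - 1)) / (n * (n - 1))
  b2 <- sum(x * (j - 1) * (j - 2)) / (n * (n - 1) * (n - 2))
  b3 <- sum(x * (j - 1) * (j - 2) * (j - 3)) / (n * (n - 1) * (n - 2) * (n - 3))
  c(beta0 = b0, beta1 = b1, beta2 = b2, beta3 = b3)
}

#' L-statistics of a sample
#'
#' The first four sample L-moments from the probability-weighted moments,
#' `L1 = beta0`, `L2 = 2 beta1 - beta0`, `L3 = 6 beta2 - 6 beta1 + beta0`,
#' `L4 = 20 beta3 - 30 beta2 + 12 beta1 - beta0`, and the derived hidden-layer
#' statistics: L-mean `LM = L1`, L-scale ratio `LS = L2 / L1`, L-skewness
#' `LSK = L3 / L2` and L-kurtosis `LK = L4 / L2`. A zero ratio denominator
#' yields 0 by convention, so constant samples map to `(c, 0, 0, 0)`.
#'
#' @param sample numeric vector, length at least 4.
#' @return named numeric vector with `L1..L4`, `LM`, `LS`, `LSK`, `LK`.
#' @export
#' @examples
#' l_statistics(c(1, 2, 3, 4))  # LM 2.5, LS 1/3, LSK 0, LK 0
l_statistics <- function(sample) {
  b <- pwm_betas(sample)
  L1 <- b[["beta0"]]
  L2 <- 2 * b[["beta1"]] - b[["beta0"]]
  L3 <- 6 * b[["beta2"]] - 6 * b[["beta1"]] + b[["beta0"]]
  L4 <- 20 * b[["beta3"]] - 30 * b[["beta2"]] + 12 * b[["beta1"]] - b[["beta0"]]
  rat <- function(num, den) if (den == 0) 0 else num / den
  c(L1 = L1, L2 = L2, L3 = L3, L4 = L4,
    LM = L1, LS = rat(L2, L1), LSK = rat(L3, L2), LK = rat(L4, L2))
}

#' L-moment descriptor of a feature vector
#'
#' The fixed (untrained) hidden layer: partitions the feature vector into
#' groups and summarises each group by its `(LM, LS, LSK, LK)` quadruple.
#' With the default `per_angle` grouping and the standard 90-angle, 256-slope
#' feature vector this yields a 360-element hidden representation.
#'
#' @param features numeric vector, typically from [extract_features()] (whose
#'   `n_angles`/`n_slopes` attributes define the `per_angle` groups), or a
#'   feature matrix (rows = images).
#' @param grouping `"per_angle"` (one group per projection angle, the
#'   default), `"per_slope"` (one group per integration-line slope, sampling
#'   across angles: with 256 slopes this gives the 1024-unit hidden layer, and
#'   is less sensitive to the cell's in-plane orientation because an angle
#'   permutation leaves each group's order statistics unchanged), `"global"`
#'   (a single group), or `"fixed_blocks"` (consecutive blocks of
#'   `block_size`).
#' @param block_size group size for `fixed_blocks`; must divide the feature
#'   length and be at least 4.
#' @param n_angles number of angle groups for `per_angle` when `features`
#'   carries no `n_angles` attribute.
#' @return numeric vector of `4 * n_groups` statistics ordered by (group,
#'   statistic); for matrix input, a matrix with one such row per image.
#' @export
lmoment_descriptor <- function(features,
                               grouping = c("per_angle", "per_slope",
                                            "global", "fixed_blocks"),
                               block_size = NULL, n_angles = NULL) {
  grouping <- match.arg(grouping)
  if (is.matrix(features)) {
    na <- n_angles %||% attr(features, "n_angles")
    out <- t(apply(features, 1, function(r)
      lmoment_descriptor(r, grouping = grouping, block_size = block_size,
                         n_angles = na)))
    return(out)
  }
  p <- length(features)
  need_angles <- function() {
    na <- n_angles %||% attr(features, "n_angles")
    if (is.null(na))
      stop_hep2(sprintf("%s grouping needs `n_angles` (attribute or argument)",
                        grouping), "hep2hos_bad_grouping")
    if (p %% na != 0)
      stop_hep2("feature length is not divisible by the number of angles",
                "hep2hos_bad_grouping")
    as.integer(na)
  }
  # features are ordered angle-major (slope fastest): a matrix with n_slopes
  # rows has one column per angle
  if (grouping == "per_slope") {
    na <- need_angles()
    if (na < 4)
      stop_hep2("per_slope grouping needs at least 4 angles",
                "hep2hos_bad_grouping")
    groups <- matrix(features, ncol = na)  # row = slope, col = angle
    return(as.vector(apply(groups, 1, function(g)
      l_statistics(g)[c("LM", "LS", "LSK", "LK")])))
  }
  gsize <- switch(grouping,
    global = p,
    per_angle = p %/% need_angles(),
    fixed_blocks = {
      if (is.null(block_size))
        stop_hep2("fixed_blocks grouping needs `block_size`",
                  "hep2hos_bad_grouping")
      if (p %% block_size != 0)
        stop_hep2("feature length is not divisible by `block_size`",
                  "hep2hos_bad_grouping")
      as.integer(block_size)
    })
  if (gsize < 4)
    stop_hep2("group size must be at least 4 (L4 undefined below that)",
              "hep2hos_bad_grouping")
  groups <- matrix(features, nrow = gsize)
  as.vector(apply(groups, 2, function(g)
    l_statistics(g)[c("LM", "LS", "LSK", "LK")]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
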
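test_that("probability-weighted moments match hand-evaluated sums", {
  b <- pwm_betas(c(1, 2, 3, 4))
  expect_equal(unname(b), c(2.5, 5 / 3, 1.25, 1))
  # internal sort: order must not matter
  expect_equal(pwm_betas(c(4, 1, 3, 2)), b)
  # constant-sample identity: 2*beta1 - beta0 = 0
  b5 <- pwm_betas(rep(5, 7))
  expect_equal(2 * b5[["beta1"]] - b5[["beta0"]], 0)
  expect_equal(b5[["beta0"]], 5)
})

test_that("short or malformed samples are rejected", {
  expect_error(pwm_betas(c(1, 2, 3)), class = "hep2hos_short_sample")
  expect_error(pwm_betas(c(1, 2, NA, 4)), class = "hep2hos_bad_sample")
})

test_that("L-statistics reproduce the worked example and conventions", {
  l <- l_statistics(c(1, 2, 3, 4))
  expect_equal(l[["LM"]], 2.5)
  expect_equal(l[["LS"]], 1 / 3)
  expect_equal(l[["LSK"]], 0)
  expect_equal(l[["LK"]], 0)
  expect_equal(l[["L2"]], 5 / 6)  # half the mean pairwise absolute difference
  # constant sample: zero-dispersion convention
  expect_equal(unname(l_statistics(rep(3.7, 6))[c("LM", "LS", "LSK", "LK")]),
               c(3.7, 0, 0, 0))
})

test_that("beta-estimator L-moments agree with U-statistic definitions", {
  set.seed(421)
  for (rep in 1:200) {
    n <- sample(4:50, 1)
    x <- switch(sample(3, 1),
                rnorm(n), rexp(n), runif(n, -2, 5))
    l <- l_statistics(x)
    u <- lmoments_ustat(x)
    expect_equal(unname(l[c("L1", "L2", "L3", "L4")]), unname(u),
                 tolerance = 1e-10)
  }
})

test_that("L-ratio bounds and affine equivariance hold", {
  set.seed(7)
  for (rep in 1:50) {
    x <- rexp(sample(5:40, 1))
    l <- l_statistics(x)
    expect_lt(abs(l[["LSK"]]), 1)
    expect_lt(abs(l[["LK"]]), 1)
    # shift: LM moves, L2 and the ratios stay
    ls <- l_statistics(x + 10)
    expect_equal(ls[["LM"]], l[["LM"]] + 10)
    expect_equal(ls[["L2"]], l[["L2"]], tolerance = 1e-12)
    expect_equal(ls[["LSK"]], l[["LSK"]], tolerance = 1e-10)
    expect_equal(ls[["LK"]], l[["LK"]], tolerance = 1e-10)
    # positive scaling: LM scales, ratios invariant
    lc <- l_statistics(3 * x)
    expect_equal(lc[["LM"]], 3 * l[["LM"]], tolerance = 1e-12)
    expect_equal(lc[["LS"]], l[["LS"]], tolerance = 1e-12)
    expect_equal(lc[["LSK"]], l[["LSK"]], tolerance = 1e-12)
    expect_equal(lc[["LK"]], l[["LK"]], tolerance = 1e-12)
  }
})

test_that("descriptor grouping produces the expected layout", {
  set.seed(3)
  feats <- structure(rnorm(90 * 256), n_angles = 90, n_slopes = 256)
  d <- lmoment_descriptor(feats, "per_angle")
  expect_length(d, 360)
  # first group's quadruple equals direct L-statistics of the first block
  expect_equal(d[1:4],
               unname(l_statistics(feats[1:256])[c("LM", "LS", "LSK", "LK")]))
  expect_length(lmoment_descriptor(feats, "global"), 4)
  expect_length(lmoment_descriptor(feats, "fixed_blocks", block_size = 256),
                360)
  # constant blocks: dispersion statistics all zero
  const <- structure(rep(2, 40), n_angles = 10)
  dc <- matrix(lmoment_descriptor(const, "per_angle"), nrow = 4)
  expect_equal(unname(dc[2, ]), rep(0, 10))
  expect_equal(unname(dc[3, ]), rep(0, 10))
  expect_equal(unname(dc[4, ]), rep(0, 10))
})

test_that("invalid groupings are rejected", {
  feats <- structure(rnorm(30), n_angles = 10)
  expect_error(lmoment_descriptor(feats, "per_angle"),
               class = "hep2hos_bad_grouping")
  expect_error(lmoment_descriptor(rnorm(12), "fixed_blocks", block_size = 3),
               class = "hep2hos_bad_grouping")
  expect_error(lmoment_descriptor(rnorm(12), "fixed_blocks", block_size = 5),
               class = "hep2hos_bad_grouping")
})
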
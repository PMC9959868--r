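test_that("confusion matrix counts land where they should", {
  y <- c(1, 2, 3, 4, 5, 6)
  cm <- confusion_matrix(y, y, 6)
  expect_equal(cm, diag(1L, 6))
  cm2 <- confusion_matrix(2, 5, 6)
  expect_equal(sum(cm2), 1)
  expect_equal(cm2[2, 5], 1L)
  # column sums are predicted-class frequencies
  set.seed(1)
  yt <- sample(6, 60, replace = TRUE)
  yp <- sample(6, 60, replace = TRUE)
  expect_equal(colSums(confusion_matrix(yt, yp, 6)), tabulate(yp, 6))
  expect_error(confusion_matrix(1:3, 1:2, 6), class = "hep2hos_dim_mismatch")
})

test_that("per-class CCR is recall and MCA its unweighted mean", {
  expect_equal(ccr_per_class(diag(5L, 4)), rep(1, 4))
  cm <- matrix(c(8, 2, 3, 7), 2, 2, byrow = TRUE)
  expect_equal(ccr_per_class(cm), c(0.8, 0.7))
  expect_equal(mca(c(0.8, 0.7)), 0.75)
  expect_equal(mca(rep(0.91, 6)), 0.91)
  # empty class: NA with a warning, excluded from MCA
  cm0 <- rbind(c(3, 0), c(0, 0))
  expect_warning(r <- ccr_per_class(cm0))
  expect_true(is.na(r[2]))
  expect_equal(mca(r), 1)
})

test_that("MCA is invariant under class relabeling", {
  set.seed(42)
  cm <- matrix(rpois(36, 20), 6, 6)
  perm <- sample(6)
  expect_equal(mca(suppressWarnings(ccr_per_class(cm))),
               mca(suppressWarnings(ccr_per_class(cm[perm, perm]))))
})

test_that("overall rate is the class-size-weighted mean of per-class rates", {
  set.seed(8)
  yt <- rep(1:6, times = c(10, 20, 5, 8, 12, 6))
  yp <- ifelse(runif(length(yt)) < 0.7, yt, sample(6, length(yt), TRUE))
  lv <- rep("positive", length(yt))
  rep_tab <- level_report(yt, yp, lv)
  per <- rep_tab[rep_tab$class != "overall", ]
  ov <- rep_tab[rep_tab$class == "overall", ]
  expect_equal(ov$rate, sum(per$rate * per$total) / sum(per$total))
  # balanced classes: overall equals the unweighted mean
  yt2 <- rep(1:6, each = 10)
  yp2 <- ifelse(runif(60) < 0.8, yt2, sample(6, 60, TRUE))
  tab2 <- level_report(yt2, yp2, rep("intermediate", 60))
  per2 <- tab2[tab2$class != "overall", ]
  expect_equal(tab2$rate[tab2$class == "overall"], mean(per2$rate))
})

test_that("published per-class counts aggregate to the published rates", {
  counts <- task1_level_counts()
  tab <- level_rates_from_counts(counts)
  pos <- tab[tab$level == "positive", ]
  int <- tab[tab$level == "intermediate", ]
  # overall positive: 3982/4513 -> 88.23 at two decimals
  expect_equal(pos$correct[pos$class == "overall"], 3982)
  expect_equal(pos$total[pos$class == "overall"], 4513)
  expect_equal(pos$rate_pct[pos$class == "overall"], 88.23)
  # overall intermediate: 4762/5583
  expect_equal(int$correct[int$class == "overall"], 4762)
  expect_equal(int$total[int$class == "overall"], 5583)
  expect_equal(int$rate[int$class == "overall"], 4762 / 5583)
  # per-class spot checks under the two-decimal convention
  expect_equal(pos$rate_pct[pos$class == "nucleolar"], 90.00)
  expect_equal(pos$rate_pct[pos$class == "centromere"], 92.45)
  expect_equal(int$rate_pct[int$class == "nucleolar"], 80.13)
})

test_that("half-up rounding follows the report convention", {
  # 955/1033 prints as 92.45
  expect_equal(hep2hos:::round_half_up(100 * 955 / 1033, 2), 92.45)
  expect_equal(hep2hos:::round_half_up(2.005, 2), 2.01)
})

test_that("level report validates its inputs", {
  expect_error(level_report(1:3, 1:3, c("positive", "bad", "positive")),
               class = "hep2hos_bad_levels")
  expect_error(level_report(1:3, 1:3, c("positive", "positive")),
               class = "hep2hos_dim_mismatch")
  # all-correct predictions print 100.00 everywhere they are defined
  tab <- level_report(rep(1:6, 2), rep(1:6, 2), rep(hep2_levels, each = 6))
  expect_true(all(tab$rate_pct[tab$total > 0] == 100))
})
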
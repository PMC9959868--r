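test_that("generation is seeded and bit-reproducible", {
  a <- generate_cell_image("speckled", "intermediate", 64, 0.02, seed = 7)
  b <- generate_cell_image("speckled", "intermediate", 64, 0.02, seed = 7)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$mask, b$mask)
  c <- generate_cell_image("speckled", "intermediate", 64, 0.02, seed = 8)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("a noiseless homogeneous nucleus is a uniform fill", {
  cell <- generate_cell_image("homogeneous", "positive", 64, 0, seed = 1)
  expect_equal(stats::sd(cell$pixels[cell$mask]), 0)
})

test_that("centromere dots form countable discrete components", {
  for (seed in c(3, 11, 25)) {
    cell <- generate_cell_image("centromere", "positive", 64, 0, seed = seed)
    fg <- cell$pixels[cell$mask]
    thr <- (max(fg) + min(fg)) / 2
    n <- flood_fill_components(cell$pixels > thr & cell$mask)
    expect_gte(n, 30)
    expect_lte(n, 60)
  }
})

test_that("images and masks satisfy their invariants across classes", {
  i <- 0
  for (cls in hep2_classes) for (lv in hep2_levels) {
    i <- i + 1
    cell <- generate_cell_image(cls, lv, 48, 0.05, seed = i)
    expect_true(all(is.finite(cell$pixels)))
    expect_true(all(cell$pixels >= 0 & cell$pixels <= 1))
    frac <- mean(cell$mask)
    expect_gte(frac, 0.05)
    expect_lte(frac, 0.95)
  }
})

test_that("bad generator arguments are rejected with clear errors", {
  expect_error(generate_cell_image("mitotic", "positive", 64),
               class = "hep2hos_bad_label")
  expect_error(generate_cell_image("golgi", "positive", 16),
               class = "hep2hos_bad_size")
})

test_that("dataset generation writes a balanced stratified manifest", {
  out <- withr::local_tempdir()
  m <- generate_dataset(10, seed = 5, out_dir = out)
  expect_equal(nrow(m), 60)
  expect_equal(sum(m$split == "train"), 48)
  expect_equal(sum(m$split == "test"), 12)
  tab <- table(m$label, m$split)
  expect_true(all(tab[, "train"] == 8))
  expect_true(all(tab[, "test"] == 2))
  expect_setequal(unique(m$label), hep2_classes)
  expect_false(any(duplicated(m$path)))
  expect_true(all(file.exists(m$path)))
  # manifest round-trips through its CSV
  m2 <- read_manifest(file.path(out, "manifest.csv"))
  expect_equal(m2$split, m$split)
  # identical seed reproduces the same split and identical image bytes
  out2 <- withr::local_tempdir()
  m3 <- generate_dataset(10, seed = 5, out_dir = out2)
  expect_equal(m3$split, m$split)
  expect_identical(readBin(m$path[1], "raw", 1e5),
                   readBin(m3$path[1], "raw", 1e5))
})

test_that("simple texture summaries separate the six classes", {
  # nearest-centroid on (foreground mean, foreground variance, bright
  # component count, boundary-band mean), one centroid per class x level
  out <- withr::local_tempdir()
  m <- generate_dataset(30, seed = 99, out_dir = out)
  summaries <- t(sapply(seq_len(nrow(m)), function(i) {
    img <- read_cell_image(m$path[i])
    mask <- read_cell_image(m$mask_path[i]) > 0.5
    fg <- img[mask]
    # bright = clearly above the typical foreground level
    thr <- stats::median(fg) + 0.12
    er <- mask & !(rbind(FALSE, mask[-nrow(mask), ]) &
                     rbind(mask[-1, ], FALSE) &
                     cbind(FALSE, mask[, -ncol(mask)]) &
                     cbind(mask[, -1], FALSE))
    # er approximates the boundary band (mask minus its erosion)
    c(mean(fg), stats::var(fg),
      flood_fill_components(img > thr & mask), mean(img[er]))
  }))
  summaries <- scale(summaries)
  key <- paste(m$label, m$intensity_level)
  cents <- t(sapply(split(as.data.frame(summaries), key), colMeans))
  nearest <- rownames(cents)[apply(summaries, 1, function(r)
    which.min(colSums((t(cents) - r)^2)))]
  acc <- mean(sub(" .*", "", nearest) == m$label)
  expect_gte(acc, 0.9)
})
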
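#' Six HEp-2 staining-pattern class labels
#'
#' The antinuclear-antibody staining patterns recognised by the classifier, in
#' the fixed order used for class indices throughout the package.
#' @export
hep2_classes <- c("homogeneous", "speckled", "nucleolar", "centromere",
                  "nuclear_membrane", "golgi")

#' Intensity levels of stained cells
#'
#' `positive` cells fluoresce at high intensity, `intermediate` cells at low
#' intensity.
#' @export
hep2_levels <- c("positive", "intermediate")

# Rasterize a disk of radius r at continuous center (y0, x0) into logical mask
# coordinates of an nr x nc grid.
.disk_mask <- function(nr, nc, y0, x0, r) {
  yy <- matrix(seq_len(nr), nr, nc)
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (yy - y0)^2 + (xx - x0)^2 <= r^2
}

# Dart-throwing placement of up to n points uniformly inside the ellipse
# (u^2 + v^2 <= shrink^2 in normalized nucleus coordinates), with minimum
# pairwise distance min_dist in pixels. Placement stops early if the nucleus
# saturates; callers must tolerate fewer points than requested.
.place_points <- function(n, center, axes, phi, shrink, min_dist,
                          max_attempts = 500L) {
  pts <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      ang <- runif(1, 0, 2 * pi)
      rad <- shrink * sqrt(runif(1))
      u <- rad * cos(ang); v <- rad * sin(ang)
      # back to pixel coordinates
      x <- center[2] + axes[1] * u * cos(phi) - axes[2] * v * sin(phi)
      y <- center[1] + axes[1] * u * sin(phi) + axes[2] * v * cos(phi)
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - y)^2 + (pts[, 2] - x)^2)) >= min_dist) {
        pts <- rbind(pts, c(y, x))
        placed <- TRUE
        break
      }
    }
    if (!placed) break
  }
  pts
}

#' Generate one synthetic HEp-2-like cell image
#'
#' Renders an elliptical nucleus with a class-specific fluorescence texture on
#' a dark background, plus the matching ground-truth nucleus mask. The six
#' texture rules follow the morphological descriptions standard in the HEp-2
#' literature:
#' \describe{
#'   \item{homogeneous}{uniform diffuse fill of the whole nucleus}
#'   \item{speckled}{dense fine-grained multiplicative speckle}
#'   \item{nucleolar}{2--5 large bright blobs on a dim fill}
#'   \item{centromere}{30--60 small discrete bright dots on a dim fill
#'     (at the default 64-pixel scale; smaller nuclei saturate below the
#'     requested count)}
#'   \item{nuclear_membrane}{bright rim along the nucleus boundary, dim
#'     interior}
#'   \item{golgi}{1--3 blobs clustered against one pole of the nucleus}
#' }
#' The bright reference level of the texture is drawn from \[0.65, 0.85\] for
#' `positive` cells and \[0.28, 0.42\] for `intermediate` cells; background
#' lies in \[0.02, 0.08\]. Additive Gaussian noise is truncated to \[0, 1\].
#' Identical arguments and `seed` give bit-identical output.
#'
#' @param label one of [hep2_classes].
#' @param intensity_level `"positive"` (high intensity) or `"intermediate"`
#'   (low intensity).
#' @param size image side length in pixels (square), at least 32.
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   intensity units.
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return list with elements `pixels` (size x size matrix in \[0,1\]), `mask`
#'   (logical nucleus mask), `label`, `intensity_level`.
#' @export
#' @examples
#' cell <- generate_cell_image("centromere", "positive", size = 64, seed = 1)
#' range(cell$pixels)
generate_cell_image <- function(label, intensity_level = "positive", size = 64L,
                                noise_sd = 0.02, seed = NULL) {
  if (!is.character(label) || length(label) != 1L || !(label %in% hep2_classes))
    stop_hep2(sprintf("unknown class label '%s'; expected one of: %s",
                      as.character(label)[1], paste(hep2_classes, collapse = ", ")),
              "hep2hos_bad_label")
  intensity_level <- match.arg(intensity_level, hep2_levels)
  if (size < 32L) stop_hep2("`size` must be at least 32 pixels", "hep2hos_bad_size")
  stopifnot(noise_sd >= 0)
  size <- as.integer(size)

  with_seed(seed, {
    # nucleus geometry: axis-aligned-ish ellipse with random eccentricity and
    # orientation; mild center jitter
    center <- (size + 1) / 2 + runif(2, -0.03, 0.03) * size
    a <- size * runif(1, 0.32, 0.38)
    b <- a * runif(1, 0.70, 1.00)
    phi <- runif(1, 0, pi)

    yy <- matrix(seq_len(size), size, size)
    xx <- matrix(seq_len(size), size, size, byrow = TRUE)
    dx <- xx - center[2]; dy <- yy - center[1]
    u <- ( dx * cos(phi) + dy * sin(phi)) / a
    v <- (-dx * sin(phi) + dy * cos(phi)) / b
    rho <- sqrt(u^2 + v^2)
    mask <- rho <= 1

    mu <- if (intensity_level == "positive") runif(1, 0.65, 0.85) else
      runif(1, 0.28, 0.42)
    bg <- runif(1, 0.02, 0.08)
    bright <- min(1, mu * 1.3)

    img <- matrix(bg, size, size)
    if (label == "homogeneous") {
      img[mask] <- mu
    } else if (label == "speckled") {
      img[mask] <- clamp01(mu * runif(sum(mask), 0.55, 1.45))
    } else if (label == "nucleolar") {
      img[mask] <- mu * 0.60
      nblob <- sample(2:5, 1)
      pts <- .place_points(nblob, center, c(a, b), phi, shrink = 0.55,
                           min_dist = 0.45 * min(a, b))
      for (i in seq_len(nrow(pts))) {
        r <- min(a, b) * runif(1, 0.14, 0.22)
        img[.disk_mask(size, size, pts[i, 1], pts[i, 2], r) & mask] <- bright
      }
    } else if (label == "centromere") {
      img[mask] <- mu * 0.55
      ndot <- sample(30:60, 1)
      pts <- .place_points(ndot, center, c(a, b), phi, shrink = 0.90,
                           min_dist = 3.5)
      for (i in seq_len(nrow(pts)))
        img[.disk_mask(size, size, pts[i, 1], pts[i, 2], 1.0) & mask] <- bright
    } else if (label == "nuclear_membrane") {
      img[mask] <- mu * 0.45
      img[mask & rho >= 0.82] <- min(1, mu * 1.2)
    } else if (label == "golgi") {
      img[mask] <- mu * 0.50
      pole <- runif(1, 0, 2 * pi)
      nblob <- sample(1:3, 1)
      for (i in seq_len(nblob)) {
        ang <- pole + runif(1, -0.45, 0.45)
        rad <- runif(1, 0.70, 0.85)
        uu <- rad * cos(ang); vv <- rad * sin(ang)
        x <- center[2] + a * uu * cos(phi) - b * vv * sin(phi)
        y <- center[1] + a * uu * sin(phi) + b * vv * cos(phi)
        r <- min(a, b) * runif(1, 0.16, 0.24)
        img[.disk_mask(size, size, y, x, r) & mask] <- bright
      }
    }

    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
    img <- clamp01(img)

    list(pixels = img, mask = mask, label = label,
         intensity_level = intensity_level)
  })
}

#' Generate a balanced synthetic six-class dataset on disk
#'
#' Writes `6 * n_per_class` cell images (8-bit grayscale PNG) with their
#' ground-truth nucleus masks and a CSV manifest, stratified into an 80/20
#' train/test split per class.
#'
#' @param n_per_class images per class (at least 2).
#' @param intensity_mix proportion of `positive`-level cells per class; the
#'   rest are `intermediate`.
#' @param size image side length in pixels.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed integer root seed; every image gets a deterministic child seed.
#' @param out_dir output directory (created if needed).
#' @param train_fraction train split fraction, stratified per class.
#' @return the manifest as a data.frame with columns `path`, `mask_path`,
#'   `label`, `intensity_level`, `split`; also written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(n_per_class, intensity_mix = 0.5, size = 64L,
                             noise_sd = 0.02, seed = 1L, out_dir,
                             train_fraction = 0.8) {
  stopifnot(n_per_class >= 2)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      stop_hep2(sprintf("cannot create output directory '%s'", out_dir),
                "hep2hos_io_error")
  }
  n_pos <- round(n_per_class * intensity_mix)

  rows <- list()
  idx <- 0L
  for (cls in hep2_classes) {
    levels_cls <- with_seed(derive_seed(seed, match(cls, hep2_classes)), {
      sample(rep(hep2_levels, c(n_pos, n_per_class - n_pos)))
    })
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      cell <- generate_cell_image(cls, levels_cls[i], size = size,
                                  noise_sd = noise_sd,
                                  seed = derive_seed(seed, 100L + idx))
      path <- file.path(out_dir, sprintf("cell_%s_%03d.png", cls, i))
      mask_path <- file.path(out_dir, sprintf("mask_%s_%03d.png", cls, i))
      write_cell_image(cell$pixels, path)
      write_cell_image(cell$mask * 1, mask_path)
      rows[[idx]] <- data.frame(path = path, mask_path = mask_path,
                                label = cls, intensity_level = levels_cls[i],
                                stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest <- split_dataset(manifest, train_fraction = train_fraction,
                            seed = derive_seed(seed, 99L))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
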
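# Intensity adjustment, cropping, rotation augmentation.

#' Linear contrast stretch between intensity quantiles
#'
#' Maps the `low_q` and `high_q` intensity quantiles to 0 and 1 and clips
#' outside. A degenerate image whose two quantiles coincide is returned
#' unchanged. Idempotent on its own output for fixed quantiles.
#'
#' @param image numeric matrix in \[0,1\].
#' @param low_q,high_q quantile probabilities, `0 <= low_q < high_q <= 1`.
#' @return adjusted matrix in \[0,1\].
#' @export
adjust_intensity <- function(image, low_q = 0.01, high_q = 0.99) {
  check_image(image)
  stopifnot(low_q >= 0, high_q <= 1, low_q < high_q)
  # inverse-ECDF quantiles (type 1) land on data values, which makes the
  # stretch exactly idempotent on its own output
  q <- stats::quantile(image, c(low_q, high_q), names = FALSE, type = 1)
  if (q[2] <= q[1]) return(image)
  clamp01((image - q[1]) / (q[2] - q[1]))
}

# Exact right-angle rotations: counterclockwise by 90 degrees (pixel
# permutation, no interpolation).
.rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Bilinear resampling of `image` to nr x nc; sample positions outside the
# source get `fill`.
resize_bilinear <- function(image, nr, nc, fill = 0) {
  h <- nrow(image); w <- ncol(image)
  # map output pixel centers onto input pixel centers
  ys <- (seq_len(nr) - 0.5) * h / nr + 0.5
  xs <- (seq_len(nc) - 0.5) * w / nc + 0.5
  .bilinear_sample(image, matrix(ys, nr, nc), matrix(xs, nr, nc, byrow = TRUE),
                   fill)
}

# Sample image at continuous (row, col) positions with bilinear interpolation.
.bilinear_sample <- function(image, ys, xs, fill = 0) {
  h <- nrow(image); w <- ncol(image)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  gv <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    out <- matrix(fill, nrow(r), ncol(r))
    out[ok] <- image[cbind(r[ok], c[ok])]
    out
  }
  (1 - fy) * (1 - fx) * gv(y0, x0) +
    (1 - fy) * fx * gv(y0, x0 + 1) +
    fy * (1 - fx) * gv(y0 + 1, x0) +
    fy * fx * gv(y0 + 1, x0 + 1)
}

#' Rotate an image about its center
#'
#' Right-angle rotations (multiples of 90 degrees) are exact pixel
#' permutations; other angles use bilinear interpolation with exposed regions
#' filled with the dark background value 0. Positive angles rotate
#' counterclockwise.
#'
#' @param image numeric matrix.
#' @param angle rotation angle in degrees.
#' @return rotated matrix with the same dimensions.
#' @export
rotate_image <- function(image, angle) {
  angle <- angle %% 360
  if (angle == 0) return(image)
  if (angle %% 90 == 0) {
    out <- image
    for (i in seq_len(angle %/% 90)) out <- .rot90_ccw(out)
    return(out)
  }
  h <- nrow(image); w <- ncol(image)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- angle * pi / 180
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse mapping: output pixel pulls from input rotated by -angle.
  # (row, col) with row increasing downwards means (x, y=-row) is a
  # right-handed frame; the formulas below rotate counterclockwise there.
  xs <- cx + cos(th) * xx + sin(th) * yy
  ys <- cy - sin(th) * xx + cos(th) * yy
  .bilinear_sample(image, ys, xs, fill = 0)
}

#' Rotation augmentation set
#'
#' Returns the input rotated to every angle `0, step, 2*step, ..., 360-step`.
#' Angle 0 reproduces the input exactly.
#'
#' @param image numeric matrix.
#' @param step_degrees angle step; must divide 360.
#' @return list with `images` (list of matrices) and `angles` (numeric vector).
#' @export
rotate_augment <- function(image, step_degrees = 90) {
  if (step_degrees <= 0 || 360 %% step_degrees != 0)
    stop_hep2("`step_degrees` must be a positive divisor of 360",
              "hep2hos_bad_step")
  angles <- seq(0, 360 - step_degrees, by = step_degrees)
  list(images = lapply(angles, function(a) rotate_image(image, a)),
       angles = angles)
}

#' Crop an image to its segmented cell and rescale
#'
#' Crops the mask's bounding box, pads it to a square with the dark background
#' value 0, and rescales to `out_size` x `out_size` with bilinear
#' interpolation.
#'
#' @param image numeric matrix.
#' @param mask logical (or 0/1) matrix of the same shape; must be nonempty.
#' @param out_size output side length in pixels (default 50, the standard
#'   single-cell crop size).
#' @return `out_size` x `out_size` numeric matrix.
#' @export
crop_to_cell <- function(image, mask, out_size = 50L) {
  stopifnot(all(dim(image) == dim(mask)))
  mask <- mask > 0
  if (!any(mask)) stop_hep2("mask is empty; nothing to crop", "hep2hos_empty_mask")
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  sub <- image[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  h <- nrow(sub); w <- ncol(sub)
  side <- max(h, w)
  sq <- matrix(0, side, side)
  r0 <- (side - h) %/% 2; c0 <- (side - w) %/% 2
  sq[r0 + seq_len(h), c0 + seq_len(w)] <- sub
  if (side == out_size) return(sq)
  resize_bilinear(sq, out_size, out_size, fill = 0)
}
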
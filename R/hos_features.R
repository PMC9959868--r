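# Higher-order-spectra features: Radon projections, bispectrum line
# integrals, bispectral-invariant phases.

#' Feature-extraction configuration
#'
#' Defaults give the standard configuration: projections every 2 degrees over
#' \[0, 180) (90 angles), FFT length 1024, 256 integration-line slopes, hence
#' `90 * 256 = 23040` features per image.
#'
#' @param angle_start,angle_stop,angle_step projection angles in degrees:
#'   every angle in `[angle_start, angle_stop)` at `angle_step` spacing.
#' @param fft_len FFT length each projection is zero-padded to.
#' @param n_slopes number of bispectrum integration lines per projection.
#' @param center subtract the projection mean before the FFT (recommended:
#'   keeps the DC term from dominating the line integrals).
#' @return a list of class `hos_config`.
#' @export
hos_config <- function(angle_start = 0, angle_stop = 180, angle_step = 2,
                       fft_len = 1024L, n_slopes = 256L, center = TRUE) {
  stopifnot(angle_start >= 0, angle_stop <= 180, angle_start < angle_stop,
            angle_step > 0, fft_len >= 2, n_slopes >= 1)
  structure(list(angle_start = angle_start, angle_stop = angle_stop,
                 angle_step = angle_step, fft_len = as.integer(fft_len),
                 n_slopes = as.integer(n_slopes), center = isTRUE(center)),
            class = "hos_config")
}

#' Radon projections of an image
#'
#' Computes the line-integral profile of the image for each angle in
#' `[angle_start, angle_stop)` at `angle_step` spacing. Each pixel's value is
#' splatted onto the two nearest projection bins with linear weights, so every
#' projection preserves the total image intensity exactly.
#'
#' @param image numeric matrix.
#' @param angle_start,angle_stop,angle_step projection angles in degrees,
#'   `0 <= angle_start < angle_stop <= 180`, `angle_step > 0`.
#' @return a list with one element per angle, each a list with `theta`
#'   (degrees) and `values` (numeric vector of line integrals).
#' @export
radon_projections <- function(image, angle_start = 0, angle_stop = 180,
                              angle_step = 2) {
  stopifnot(is.matrix(image), is.numeric(image))
  stopifnot(angle_start >= 0, angle_stop <= 180, angle_step > 0)
  if (angle_start >= angle_stop)
    stop_hep2("empty angle range", "hep2hos_bad_angles")
  angles <- seq(angle_start, angle_stop, by = angle_step)
  angles <- angles[angles < angle_stop]
  if (length(angles) == 0)
    stop_hep2("empty angle set", "hep2hos_bad_angles")

  h <- nrow(image); w <- ncol(image)
  dy <- matrix(seq_len(h), h, w) - (h + 1) / 2
  dx <- matrix(seq_len(w), h, w, byrow = TRUE) - (w + 1) / 2
  tmax <- ceiling(sqrt(h^2 + w^2) / 2)
  off <- tmax + 2L
  nb <- 2L * tmax + 4L
  v <- as.vector(image)

  lapply(angles, function(theta) {
    t <- as.vector(dx * cospi(theta / 180) + dy * sinpi(theta / 180))
    i0 <- floor(t)
    fr <- t - i0
    proj <- numeric(nb)
    r <- rowsum(c(v * (1 - fr), v * fr), c(i0 + off, i0 + off + 1L))
    proj[as.integer(rownames(r))] <- r
    list(theta = theta, values = proj)
  })
}

#' Bispectral-invariant phases of one projection
#'
#' The projection is mean-subtracted, zero-padded to `fft_len`, and Fourier
#' transformed. For each slope `a_i = i / n_slopes` (`i = 1..n_slopes`) the
#' bispectrum `S(k1, k2) = F(k1) F(k2) conj(F(k1 + k2))` is accumulated along
#' the line `k2 = a_i k1` over the grid frequencies `0 < k1 <= 1 / (1 + a_i)`
#' (normalised so the Nyquist frequency is 1), with `S` interpolated linearly
#' between the two bracketing grid values at non-grid `k2`. The returned
#' feature is the phase `P(a_i) = atan2(Im I, Re I)` of each line integral:
#' invariant to translation of the signal and to positive amplitude scaling.
#'
#' @param projection a projection as returned by [radon_projections()] or a
#'   bare numeric vector.
#' @param fft_len FFT length, at least the projection length.
#' @param n_slopes number of integration-line slopes.
#' @param center subtract the mean before the FFT. Disable to study raw
#'   spectra (e.g. a single impulse yields exactly zero phases).
#' @return numeric vector of `n_slopes` phases in `(-pi, pi]`; an all-zero
#'   projection yields all-zero phases by convention.
#' @export
bispectral_invariants <- function(projection, fft_len = 1024L,
                                  n_slopes = 256L, center = TRUE) {
  x <- if (is.list(projection)) projection$values else projection
  if (length(x) == 0)
    stop_hep2("empty projection", "hep2hos_bad_projection")
  if (fft_len < length(x))
    stop_hep2("`fft_len` must be at least the projection length",
              "hep2hos_bad_fft_len")
  if (all(x == 0)) return(numeric(n_slopes))
  if (center) x <- x - mean(x)
  xp <- c(x, numeric(fft_len - length(x)))
  F <- stats::fft(xp)
  I <- bispec_line_integrals(F, as.integer(n_slopes))
  atan2(Im(I), Re(I))
}

#' Extract the full higher-order-spectra feature vector of an image
#'
#' Concatenates [bispectral_invariants()] over all Radon projection angles,
#' ordered by (angle index, slope index). With the default configuration (90
#' angles, 256 slopes) the vector has 23040 elements.
#'
#' @param image numeric matrix in \[0,1\].
#' @param config an [hos_config()].
#' @return numeric vector of length `n_angles * n_slopes` with attributes
#'   `n_angles`, `n_slopes`.
#' @export
extract_features <- function(image, config = hos_config()) {
  check_image(image)
  stopifnot(inherits(config, "hos_config"))
  projs <- radon_projections(image, config$angle_start, config$angle_stop,
                             config$angle_step)
  feats <- unlist(lapply(projs, function(p)
    bispectral_invariants(p, fft_len = config$fft_len,
                          n_slopes = config$n_slopes,
                          center = config$center)), use.names = FALSE)
  structure(feats, n_angles = length(projs), n_slopes = config$n_slopes)
}

#' Extract features for a batch of images
#'
#' @param images list of numeric matrices.
#' @param config an [hos_config()].
#' @return matrix (rows = images) with attributes `n_angles`, `n_slopes`.
#' @export
extract_features_batch <- function(images, config = hos_config()) {
  rows <- lapply(images, extract_features, config = config)
  x <- do.call(rbind, rows)
  attr(x, "n_angles") <- attr(rows[[1]], "n_angles")
  attr(x, "n_slopes") <- attr(rows[[1]], "n_slopes")
  x
}
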
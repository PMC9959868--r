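# Edge-based geometric active contour (morphological level set) segmentation.

# Shift a matrix by (dr, dc), filling exposed entries with `fill`.
.shift_mat <- function(m, dr, dc, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- seq_len(h) - dr; cs <- seq_len(w) - dc
  rok <- rs >= 1 & rs <= h; cok <- cs >= 1 & cs <= w
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

.dilate3 <- function(u) {
  out <- u
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) out <- pmax(out, .shift_mat(u, dr, dc, 0))
  out
}

.erode3 <- function(u) {
  out <- u
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) out <- pmin(out, .shift_mat(u, dr, dc, 1))
  out
}

# Curvature morphology: sup-inf (SI) and inf-sup (IS) over the four
# 3-pixel line structuring elements.
.line_offsets <- list(rbind(c(0, -1), c(0, 0), c(0, 1)),
                      rbind(c(-1, 0), c(0, 0), c(1, 0)),
                      rbind(c(-1, -1), c(0, 0), c(1, 1)),
                      rbind(c(-1, 1), c(0, 0), c(1, -1)))

.sup_inf <- function(u) {
  res <- matrix(0, nrow(u), ncol(u))
  for (off in .line_offsets) {
    m <- matrix(1, nrow(u), ncol(u))
    for (i in seq_len(nrow(off)))
      m <- pmin(m, .shift_mat(u, off[i, 1], off[i, 2], 1))
    res <- pmax(res, m)
  }
  res
}

.inf_sup <- function(u) {
  res <- matrix(1, nrow(u), ncol(u))
  for (off in .line_offsets) {
    m <- matrix(0, nrow(u), ncol(u))
    for (i in seq_len(nrow(off)))
      m <- pmax(m, .shift_mat(u, off[i, 1], off[i, 2], 0))
    res <- pmin(res, m)
  }
  res
}

# Separable Gaussian blur with replicated edges.
.gauss_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  r <- ceiling(3 * sigma)
  k <- exp(-(( -r:r )^2) / (2 * sigma^2)); k <- k / sum(k)
  conv1 <- function(m) {
    h <- nrow(m)
    out <- matrix(0, h, ncol(m))
    for (i in -r:r) {
      idx <- pmin(pmax(seq_len(h) + i, 1L), h)
      out <- out + k[i + r + 1] * m[idx, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(image))))
}

# Central-difference gradient with replicated edges; returns list(dy, dx).
.gradient <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- m[pmin(pmax(seq_len(h) + 1, 1), h), , drop = FALSE]
  dn <- m[pmin(pmax(seq_len(h) - 1, 1), h), , drop = FALSE]
  le <- m[, pmin(pmax(seq_len(w) - 1, 1), w), drop = FALSE]
  ri <- m[, pmin(pmax(seq_len(w) + 1, 1), w), drop = FALSE]
  list(dy = (up - dn) / 2, dx = (ri - le) / 2)
}

#' Inverse-gradient edge-stopping map
#'
#' `g = 1 / sqrt(1 + alpha * |grad(G_sigma * image)|)`: close to 1 in flat
#' regions, small on intensity edges.
#' @param image numeric matrix in \[0,1\].
#' @param alpha edge sensitivity; larger values suppress weaker edges harder.
#' @param sigma Gaussian presmoothing scale in pixels.
#' @return matrix in (0, 1\].
#' @export
edge_indicator <- function(image, alpha = 500, sigma = 2) {
  gr <- .gradient(.gauss_blur(image, sigma))
  1 / sqrt(1 + alpha * sqrt(gr$dx^2 + gr$dy^2))
}

#' Segment a cell with a morphological geodesic active contour
#'
#' Evolves a binary level set under the standard morphological approximation
#' of the edge-based geometric active contour: a balloon force (dilation or
#' erosion, frozen where the edge-stopping map is small), an image-attachment
#' step aligning the front with the gradient of the edge map, and curvature
#' regularisation by alternating sup-inf / inf-sup line morphology. The
#' contour is initialised from the pixels above the `seed_quantile` intensity
#' quantile. The returned mask is the largest connected foreground component
#' with holes filled.
#'
#' @param image numeric matrix in \[0,1\].
#' @param iterations evolution steps (each moves the front at most one pixel).
#' @param smoothing curvature-smoothing passes per step (0 = none).
#' @param balloon signed balloon speed: positive inflates, negative deflates,
#'   0 disables.
#' @param alpha,sigma edge-stopping parameters, see [edge_indicator()].
#' @param seed_quantile intensity quantile (strictly) above which pixels seed
#'   the initial region.
#' @param threshold edge-map value below which the balloon force is frozen;
#'   default is the 40th percentile of the edge map.
#' @return logical mask matrix (single connected component, holes filled).
#'   Signals an error of class `hep2hos_segfail` if the evolution collapses to
#'   an empty region.
#' @export
segment_gac <- function(image, iterations = 100L, smoothing = 2L, balloon = 1,
                        alpha = 500, sigma = 2, seed_quantile = 0.75,
                        threshold = NULL) {
  check_image(image)
  g <- edge_indicator(image, alpha = alpha, sigma = sigma)
  if (is.null(threshold)) threshold <- stats::quantile(g, 0.4, names = FALSE)
  dg <- .gradient(g)
  thr_seed <- stats::quantile(image, seed_quantile, names = FALSE)
  u <- (image > thr_seed) * 1
  # plateau at the quantile (e.g. a saturated object): take the closed level set
  if (!any(u > 0) && thr_seed > min(image)) u <- (image >= thr_seed) * 1
  if (!any(u > 0))
    stop_hep2("no seed region: image has no pixels above the seed quantile",
              "hep2hos_segfail")
  balloon_mask <- g > threshold / max(abs(balloon), .Machine$double.eps)

  for (it in seq_len(iterations)) {
    if (balloon > 0) {
      aux <- .dilate3(u)
      u[balloon_mask] <- aux[balloon_mask]
    } else if (balloon < 0) {
      aux <- .erode3(u)
      u[balloon_mask] <- aux[balloon_mask]
    }
    du <- .gradient(u)
    att <- dg$dx * du$dx + dg$dy * du$dy
    u[att > 0] <- 1
    u[att < 0] <- 0
    if (smoothing > 0) {
      for (s in seq_len(smoothing)) {
        u <- if ((it + s) %% 2 == 0) .sup_inf(.inf_sup(u)) else
          .inf_sup(.sup_inf(u))
      }
    }
    if (!any(u > 0))
      stop_hep2("active contour collapsed to an empty region",
                "hep2hos_segfail")
  }
  .largest_filled_component(u > 0)
}

# Largest connected foreground component with holes filled.
.largest_filled_component <- function(mask) {
  if (!any(mask))
    stop_hep2("segmentation produced an empty mask", "hep2hos_segfail")
  lab <- EBImage::bwlabel(mask * 1)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  comp <- (lab == keep) * 1
  EBImage::fillHull(comp) > 0
}

#' Otsu-threshold segmentation (fallback)
#'
#' Thresholds at the Otsu level, keeps the largest connected component and
#' fills holes.
#' @inheritParams segment_gac
#' @return logical mask matrix.
#' @export
segment_otsu <- function(image) {
  check_image(image)
  if (max(image) <= min(image))
    stop_hep2("constant image cannot be segmented", "hep2hos_segfail")
  thr <- EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  m <- image > thr
  if (!any(m)) stop_hep2("Otsu threshold left no foreground", "hep2hos_segfail")
  .largest_filled_component(m)
}

#' Segment a cell, falling back to Otsu thresholding on failure
#'
#' Runs [segment_gac()]; if the contour collapses (or errors), falls back to
#' [segment_otsu()] so batch pipelines never dead-end.
#' @inheritParams segment_gac
#' @param ... passed to [segment_gac()].
#' @return logical mask matrix.
#' @export
segment_cell <- function(image, ...) {
  tryCatch(segment_gac(image, ...),
           hep2hos_segfail = function(e) segment_otsu(image))
}
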
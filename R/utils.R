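#' @useDynLib hep2hos, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft quantile rnorm runif sd
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL leaves the global RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed for item i of a root seed; stays below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483587)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Half-up rounding to `digits` decimals (report convention; base round() is
# round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

stop_hep2 <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hep2hos_error")))
}

check_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop_hep2(sprintf("`%s` must be a numeric matrix", arg), "hep2hos_bad_image")
  if (nrow(image) < 16L || ncol(image) < 16L)
    stop_hep2(sprintf("`%s` must be at least 16x16 pixels", arg), "hep2hos_bad_image")
  if (any(!is.finite(image)) || any(image < 0) || any(image > 1))
    stop_hep2(sprintf("`%s` must have finite intensities in [0, 1]", arg),
              "hep2hos_bad_image")
  invisible(image)
}
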
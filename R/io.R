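# Grayscale image and artifact I/O.

#' Read a grayscale cell image
#'
#' Reads a PNG (any bit depth) as a numeric matrix in \[0,1\]; colour images
#' are averaged to grayscale.
#' @param path file path.
#' @return numeric matrix (rows = image rows).
#' @export
read_cell_image <- function(path) {
  if (!file.exists(path))
    stop_hep2(sprintf("image file '%s' does not exist", path), "hep2hos_io_error")
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE],
                                           c(1, 2), mean)
  clamp01(img)
}

#' Write a grayscale cell image as 8-bit PNG
#' @param image numeric matrix in \[0,1\].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_cell_image <- function(image, path) {
  png::writePNG(clamp01(image), path)
  invisible(path)
}

#' Read a dataset manifest CSV
#' @param path path to a manifest CSV with columns `path`, `label`,
#'   `intensity_level`, `split` (and optionally `mask_path`).
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "label", "intensity_level", "split")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop_hep2(sprintf("manifest is missing columns: %s",
                      paste(missing, collapse = ", ")), "hep2hos_bad_manifest")
  bad <- setdiff(unique(m$label), hep2_classes)
  if (length(bad))
    stop_hep2(sprintf("manifest contains unknown labels: %s",
                      paste(bad, collapse = ", ")), "hep2hos_bad_manifest")
  m
}

#' Write a feature or descriptor matrix with a JSON sidecar
#'
#' The matrix is written as CSV (rows = images); extraction settings go into
#' `<path>.json` so the matrix is self-describing.
#' @param x numeric matrix.
#' @param path destination CSV path.
#' @param meta named list recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path, meta = list()) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a feature or descriptor matrix written by [write_feature_matrix()]
#' @param path CSV path.
#' @return numeric matrix with attribute `meta` (the sidecar, if present).
#' @export
read_feature_matrix <- function(path) {
  x <- as.matrix(utils::read.csv(path))
  side <- paste0(path, ".json")
  if (file.exists(side)) attr(x, "meta") <- jsonlite::read_json(side)
  x
}

#' Save a fitted model as a plain-text archive
#'
#' Writes `W.csv`, `b.csv`, `trace.csv` and a JSON header (dimensions,
#' hyperparameters, descriptor configuration, format version) into a
#' directory.
#' @param object a [hosnet] fit or a bare `softmax_fit` result.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(object, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(object$W), file.path(dir, "W.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(b = object$b), file.path(dir, "b.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(iteration = seq_along(object$trace),
                              cost = object$trace),
                   file.path(dir, "trace.csv"), row.names = FALSE)
  header <- list(
    format_version = 1L,
    m = nrow(object$W), k = ncol(object$W),
    eta = object$eta, lambda = object$lambda,
    iterations = object$iterations,
    classes = object$classes,
    grouping = object$grouping,
    n_angles = object$n_angles,
    block_size = object$block_size,
    standardize = isTRUE(object$standardize),
    feature_config = object$feature_config,
    center = object$center, scale = object$scale
  )
  jsonlite::write_json(header, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a model archive written by [save_model()]
#' @param dir archive directory.
#' @return an object of class `hosnet`.
#' @export
load_model <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "model.json"),
                                simplifyVector = TRUE)
  W <- as.matrix(utils::read.csv(file.path(dir, "W.csv")))
  dimnames(W) <- NULL
  b <- utils::read.csv(file.path(dir, "b.csv"))$b
  trace <- utils::read.csv(file.path(dir, "trace.csv"))$cost
  fit <- list(W = W, b = b, trace = trace, eta = header$eta,
              lambda = header$lambda, iterations = header$iterations,
              classes = header$classes, grouping = header$grouping,
              n_angles = header$n_angles, block_size = header$block_size,
              standardize = isTRUE(header$standardize),
              feature_config = header$feature_config,
              center = if (length(header$center)) unlist(header$center) else NULL,
              scale = if (length(header$scale)) unlist(header$scale) else NULL)
  class(fit) <- "hosnet"
  fit
}
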
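# End-to-end orchestration: generate -> segment -> extract -> train ->
# evaluate.

#' Pipeline configuration
#'
#' All knobs of the end-to-end pipeline in one JSON-serialisable list.
#' Randomness everywhere flows from the single root `seed`.
#'
#' @param n_per_class synthetic images per class.
#' @param intensity_mix proportion of positive-level cells.
#' @param image_size generated image side length in pixels.
#' @param noise_sd generator noise standard deviation.
#' @param low_q,high_q contrast-stretch quantiles, see [adjust_intensity()].
#' @param gac_iterations,smoothing,balloon segmentation parameters, see
#'   [segment_gac()].
#' @param crop_size cell crop side length in pixels.
#' @param aug_step rotation-augmentation angle step in degrees for training
#'   images (must divide 360); 0 disables augmentation.
#' @param angle_step,n_slopes,fft_len feature extraction, see [hos_config()].
#' @param grouping descriptor grouping, see [lmoment_descriptor()].
#' @param eta,iterations,lambda,init training, see [softmax_fit()].
#' @param train_fraction stratified train split fraction.
#' @param seed root seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_per_class = 50L, intensity_mix = 0.5,
                            image_size = 64L, noise_sd = 0.02,
                            low_q = 0.01, high_q = 0.99,
                            gac_iterations = 100L, smoothing = 2L, balloon = 1,
                            crop_size = 50L, aug_step = 90,
                            angle_step = 2, n_slopes = 256L, fft_len = 1024L,
                            grouping = "per_angle", eta = 0.01,
                            iterations = 500L, lambda = 0.01,
                            init = "uniform", train_fraction = 0.8,
                            seed = 42L) {
  if (aug_step != 0 && (aug_step < 0 || 360 %% aug_step != 0))
    stop_hep2("`aug_step` must be 0 or a positive divisor of 360",
              "hep2hos_bad_step")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `path` (write) or the configuration (read).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

#' Stratified train/test split of a manifest
#'
#' Assigns each record to `train` or `test`, stratified per class at the
#' given fraction (at least one record per class on each side when possible).
#'
#' @param manifest data.frame with a `label` column.
#' @param train_fraction fraction in (0, 1), exclusive.
#' @param seed integer seed.
#' @return the manifest with a `split` column.
#' @export
split_dataset <- function(manifest, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_hep2("`train_fraction` must lie strictly between 0 and 1",
              "hep2hos_bad_fraction")
  manifest$split <- NA_character_
  with_seed(seed, {
    for (cls in unique(manifest$label)) {
      idx <- which(manifest$label == cls)
      n <- length(idx)
      n_train <- max(1L, floor(n * train_fraction))
      if (n_train == n) n_train <- n - 1L
      tr <- sample(idx, n_train)
      manifest$split[tr] <- "train"
      manifest$split[setdiff(idx, tr)] <- "test"
    }
  })
  manifest
}

# Segment, mask and crop one image; background is zeroed so the Radon
# features see only the cell.
.prep_one <- function(image, config) {
  adj <- adjust_intensity(image, config$low_q, config$high_q)
  mask <- segment_cell(adj, iterations = config$gac_iterations,
                       smoothing = config$smoothing, balloon = config$balloon)
  crop_to_cell(adj * mask, mask, out_size = config$crop_size)
}

#' Run the full classification pipeline
#'
#' Generates (or loads) the dataset, segments and crops every cell, rotation-
#' augments the training split, extracts higher-order-spectra features, trains
#' the L-moment softmax network, and evaluates on the held-out test split.
#' Intermediate artifacts (manifest, descriptor matrix, model archive,
#' report) are persisted under `out_dir`, along with a log recording each
#' stage's parameters and record counts and the configuration hash.
#'
#' @param config a [pipeline_config()].
#' @param out_dir working directory for artifacts (created if needed).
#' @param manifest optional pre-existing manifest data.frame (columns `path`,
#'   `label`, `intensity_level`, `split`); when supplied, generation is
#'   skipped and images are read from `path`.
#' @return list of class `hep2_pipeline` with `report` (an `hep2_eval`),
#'   `model` (an [hosnet] fit), `manifest` and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("hep2_"),
                         manifest = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  write_config(config, cfg_path)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(stage, fmt, ...) {
    cat(sprintf("[%s] %s\n", stage, sprintf(fmt, ...)), file = log_path,
        append = TRUE)
  }
  cat(sprintf("config md5: %s\n", unname(tools::md5sum(cfg_path))),
      file = log_path)

  stage <- "generate"
  res <- tryCatch({
    if (is.null(manifest)) {
      manifest <- generate_dataset(config$n_per_class, config$intensity_mix,
                                   size = config$image_size,
                                   noise_sd = config$noise_sd,
                                   seed = config$seed,
                                   out_dir = file.path(out_dir, "data"),
                                   train_fraction = config$train_fraction)
    }
    logf(stage, "%d records (%d train / %d test)", nrow(manifest),
         sum(manifest$split == "train"), sum(manifest$split == "test"))

    stage <- "segment"
    crops <- lapply(manifest$path, function(p)
      .prep_one(read_cell_image(p), config))
    logf(stage, "%d cells segmented and cropped to %dx%d", length(crops),
         config$crop_size, config$crop_size)

    stage <- "augment"
    is_train <- manifest$split == "train"
    if (config$aug_step > 0) {
      train_idx <- which(is_train)
      aug <- lapply(train_idx, function(i)
        rotate_augment(crops[[i]], config$aug_step)$images)
      train_imgs <- do.call(c, aug)
      train_meta <- manifest[rep(train_idx,
                                 each = 360 %/% config$aug_step), ]
    } else {
      train_imgs <- crops[is_train]
      train_meta <- manifest[is_train, ]
    }
    logf(stage, "aug_step = %g: %d training images", config$aug_step,
         length(train_imgs))

    stage <- "extract"
    hc <- hos_config(angle_step = config$angle_step,
                     n_slopes = config$n_slopes, fft_len = config$fft_len)
    Xtr <- extract_features_batch(train_imgs, hc)
    Xte <- extract_features_batch(crops[!is_train], hc)
    logf(stage, "%d features per image", ncol(Xtr))

    stage <- "train"
    model <- hosnet(Xtr, train_meta$label, grouping = config$grouping,
                    eta = config$eta, iterations = config$iterations,
                    lambda = config$lambda, seed = derive_seed(config$seed, 7L),
                    init = config$init)
    logf(stage, "final cost %.6f", model$trace[length(model$trace)])

    stage <- "evaluate"
    test_meta <- manifest[!is_train, ]
    pred <- predict(model, Xte)
    report <- evaluate_predictions(factor(test_meta$label, model$classes),
                                   pred, classes = model$classes,
                                   levels = test_meta$intensity_level)
    logf(stage, "MCA %.4f on %d test images", report$mca, nrow(test_meta))

    stage <- "persist"
    write_feature_matrix(model$descriptors,
                         file.path(out_dir, "descriptors.csv"),
                         meta = list(grouping = config$grouping,
                                     n_angles = attr(Xtr, "n_angles"),
                                     n_slopes = config$n_slopes,
                                     fft_len = config$fft_len,
                                     angle_step = config$angle_step))
    save_model(model, file.path(out_dir, "model"))
    rep_df <- data.frame(class = model$classes, ccr = report$ccr)
    utils::write.csv(rep_df, file.path(out_dir, "report_ccr.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(report$per_level),
                     file.path(out_dir, "report_levels.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(mca = report$mca),
                     file.path(out_dir, "report_mca.csv"), row.names = FALSE)

    structure(list(report = report, model = model, manifest = manifest,
                   config = config, out_dir = out_dir),
              class = "hep2_pipeline")
  }, error = function(e) {
    if (inherits(e, "hep2hos_error"))
      stop_hep2(sprintf("pipeline failed at stage '%s': %s", stage,
                        conditionMessage(e)), "hep2hos_pipeline_error")
    stop(e)
  })
  res
}

#' @export
print.hep2_pipeline <- function(x, ...) {
  cat(sprintf("HEp-2 classification pipeline (%d images, seed %s)\n",
              nrow(x$manifest), as.character(x$config$seed)))
  cat(sprintf("  augmentation step: %g\n", x$config$aug_step))
  print(x$report)
  invisible(x)
}

#' Augmentation ablation: train with and without rotation augmentation
#'
#' Runs the pipeline once up to feature extraction, then trains the network
#' twice on the identical split — once on the plain training crops and once
#' with rotation augmentation at `config$aug_step` — and evaluates both on
#' the same held-out test images. Generation, segmentation and test-image
#' feature extraction are shared between the two arms, so the comparison
#' isolates the effect of augmentation.
#'
#' @param config a [pipeline_config()]; `aug_step` must be positive.
#' @param out_dir working directory for artifacts.
#' @return list of class `hep2_aug_comparison` with elements `unaugmented`
#'   and `augmented` (each an `hep2_eval` report plus the fitted model),
#'   `manifest` and `config`.
#' @export
run_augmentation_comparison <- function(config = pipeline_config(),
                                        out_dir = tempfile("hep2_")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$aug_step <= 0)
    stop_hep2("`aug_step` must be positive for an augmentation comparison",
              "hep2hos_bad_step")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- generate_dataset(config$n_per_class, config$intensity_mix,
                               size = config$image_size,
                               noise_sd = config$noise_sd, seed = config$seed,
                               out_dir = file.path(out_dir, "data"),
                               train_fraction = config$train_fraction)
  crops <- lapply(manifest$path, function(p)
    .prep_one(read_cell_image(p), config))
  is_train <- manifest$split == "train"
  train_idx <- which(is_train)
  hc <- hos_config(angle_step = config$angle_step,
                   n_slopes = config$n_slopes, fft_len = config$fft_len)

  Xtr <- extract_features_batch(crops[train_idx], hc)
  Xte <- extract_features_batch(crops[!is_train], hc)
  # extra rotated copies for the augmented arm (angle 0 is the plain crop)
  extra_angles <- seq(config$aug_step, 360 - config$aug_step,
                      by = config$aug_step)
  Xrot <- extract_features_batch(
    do.call(c, lapply(extra_angles, function(a)
      lapply(crops[train_idx], rotate_image, angle = a))), hc)
  Xaug <- rbind(Xtr, Xrot)
  attr(Xaug, "n_angles") <- attr(Xtr, "n_angles")
  lab_tr <- manifest$label[train_idx]
  lab_aug <- rep(lab_tr, 1 + length(extra_angles))

  test_meta <- manifest[!is_train, ]
  arm <- function(X, labels) {
    model <- hosnet(X, labels, grouping = config$grouping, eta = config$eta,
                    iterations = config$iterations, lambda = config$lambda,
                    seed = derive_seed(config$seed, 7L), init = config$init)
    report <- evaluate_predictions(factor(test_meta$label, model$classes),
                                   predict(model, Xte),
                                   classes = model$classes,
                                   levels = test_meta$intensity_level)
    list(model = model, report = report)
  }
  res <- list(unaugmented = arm(Xtr, lab_tr), augmented = arm(Xaug, lab_aug),
              manifest = manifest, config = config)
  class(res) <- "hep2_aug_comparison"
  utils::write.csv(
    data.frame(arm = c("unaugmented", "augmented"),
               mca = c(res$unaugmented$report$mca, res$augmented$report$mca)),
    file.path(out_dir, "augmentation_mca.csv"), row.names = FALSE)
  res
}

#' @export
print.hep2_aug_comparison <- function(x, ...) {
  cat(sprintf("Rotation-augmentation ablation (step %g deg, seed %s)\n",
              x$config$aug_step, as.character(x$config$seed)))
  cat(sprintf("  unaugmented MCA: %.4f\n", x$unaugmented$report$mca))
  cat(sprintf("  augmented MCA:   %.4f\n", x$augmented$report$mca))
  invisible(x)
}
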
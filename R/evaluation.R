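# Confusion matrix, per-class correct-classification rates, mean class
# accuracy, positive/intermediate report.

#' Confusion matrix
#'
#' @param y_true,y_pred integer class indices in `1..k` (factors are converted
#'   using their integer codes), equal lengths.
#' @param k number of classes.
#' @return k x k integer matrix, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(y_true, y_pred, k) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop_hep2("y_true and y_pred must have equal length", "hep2hos_dim_mismatch")
  if (any(y_true < 1 | y_true > k | y_pred < 1 | y_pred > k))
    stop_hep2(sprintf("labels must lie in 1..%d", k), "hep2hos_bad_labels")
  cm <- matrix(0L, k, k)
  for (i in seq_along(y_true))
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  cm
}

#' Per-class correct classification rate
#'
#' The contest metric: per-class recall `counts[n, n] / rowsum_n`. Classes
#' with no evaluated samples get `NA` with a warning (and are excluded from
#' [mca()] via `na.rm`).
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @return numeric vector of k rates in \[0, 1\] (NA for empty classes).
#' @export
ccr_per_class <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  tot <- rowSums(cm)
  if (any(tot == 0))
    warning("some classes have no evaluated samples; their CCR is NA")
  ifelse(tot > 0, diag(cm) / tot, NA_real_)
}

#' Mean class accuracy
#'
#' Unweighted arithmetic mean of the per-class correct classification rates.
#'
#' @param rates per-class rates, possibly with NAs for empty classes.
#' @return scalar MCA.
#' @export
mca <- function(rates) {
  ok <- !is.na(rates)
  if (!any(ok)) stop_hep2("no defined per-class rates", "hep2hos_bad_rates")
  mean(rates[ok])
}

#' Per-class rates from a counts table
#'
#' Computes per-class and overall rates (in percent, rounded half-up to two
#' decimals for printing; full precision kept in `rate`) from a table of
#' correct/total counts per class and intensity level.
#'
#' @param counts data.frame with columns `class`, `level`, `correct`, `total`.
#' @return data.frame with per-class rows plus one `overall` row per level;
#'   columns `class`, `level`, `correct`, `total`, `rate` (proportion) and
#'   `rate_pct` (percent, 2 decimals, half-up).
#' @export
level_rates_from_counts <- function(counts) {
  stopifnot(all(c("class", "level", "correct", "total") %in% names(counts)))
  if (any(counts$correct > counts$total) || any(counts$total < 0))
    stop_hep2("invalid counts: need 0 <= correct <= total", "hep2hos_bad_counts")
  out <- do.call(rbind, lapply(split(counts, counts$level), function(d) {
    overall <- data.frame(class = "overall", level = d$level[1],
                          correct = sum(d$correct), total = sum(d$total))
    rbind(d[, c("class", "level", "correct", "total")], overall)
  }))
  rownames(out) <- NULL
  out$rate <- ifelse(out$total > 0, out$correct / out$total, NA_real_)
  out$rate_pct <- round_half_up(100 * out$rate, 2)
  out
}

#' Positive/intermediate per-class accuracy report
#'
#' For each class and intensity level, the number of correctly classified
#' cells, the number evaluated, and the rate in percent (two decimals,
#' half-up), plus an overall row per level aggregating the counts.
#'
#' @param y_true,y_pred integer class indices in `1..k` or factors.
#' @param levels character vector of per-sample intensity levels
#'   (`"positive"`/`"intermediate"`).
#' @param classes class names (default [hep2_classes]).
#' @return data.frame of class `hep2_level_report`, see
#'   [level_rates_from_counts()] for columns.
#' @export
level_report <- function(y_true, y_pred, levels, classes = hep2_classes) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(levels) != length(y_true))
    stop_hep2("every sample needs a level tag", "hep2hos_dim_mismatch")
  bad <- setdiff(unique(levels), hep2_levels)
  if (length(bad))
    stop_hep2(sprintf("unknown level tag(s): %s", paste(bad, collapse = ", ")),
              "hep2hos_bad_levels")
  rows <- list()
  for (lv in intersect(hep2_levels, unique(levels))) {
    sel <- levels == lv
    for (ci in seq_along(classes)) {
      in_class <- sel & y_true == ci
      rows[[length(rows) + 1L]] <- data.frame(
        class = classes[ci], level = lv,
        correct = sum(in_class & y_pred == ci), total = sum(in_class))
    }
  }
  out <- level_rates_from_counts(do.call(rbind, rows))
  class(out) <- c("hep2_level_report", class(out))
  out
}

#' @export
print.hep2_level_report <- function(x, ...) {
  cat("Per-class accuracy by intensity level\n")
  for (lv in unique(x$level)) {
    d <- x[x$level == lv, ]
    cat(sprintf("\n  %s cells\n", lv))
    for (i in seq_len(nrow(d)))
      cat(sprintf("    %-18s %6d/%-6d %s\n", d$class[i], d$correct[i],
                  d$total[i],
                  if (is.na(d$rate_pct[i])) "-" else
                    sprintf("%.2f%%", d$rate_pct[i])))
  }
  invisible(x)
}

#' Published Task-1 per-class evaluation counts
#'
#' The per-class correct/total counts reported for the bispectral L-moment
#' classifier on the ICPR Task-1 HEp-2 cell benchmark, by intensity level
#' (positive / intermediate). Bundled as reference input for report-format
#' checks: aggregating these counts reproduces the published overall rates.
#'
#' @return data.frame with columns `class`, `level`, `correct`, `total`.
#' @export
task1_level_counts <- function() {
  path <- system.file("extdata", "task1_level_counts.csv", package = "hep2hos",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Full evaluation report
#'
#' Confusion matrix, per-class CCR, MCA, and (when level tags are supplied)
#' the positive/intermediate table.
#'
#' @inheritParams level_report
#' @param levels optional per-sample intensity levels.
#' @return list of class `hep2_eval` with `confusion`, `ccr`, `mca`,
#'   `per_level` (or NULL).
#' @export
evaluate_predictions <- function(y_true, y_pred, classes = hep2_classes,
                                 levels = NULL) {
  k <- length(classes)
  cm <- confusion_matrix(y_true, y_pred, k)
  dimnames(cm) <- list(true = classes, predicted = classes)
  rates <- suppressWarnings(ccr_per_class(cm))
  names(rates) <- classes
  out <- list(confusion = cm, ccr = rates, mca = mca(rates),
              per_level = if (!is.null(levels))
                level_report(y_true, y_pred, levels, classes))
  class(out) <- "hep2_eval"
  out
}

#' @export
print.hep2_eval <- function(x, ...) {
  cat("Evaluation report\n\nConfusion matrix:\n")
  print(x$confusion)
  cat("\nPer-class CCR:\n")
  print(round(x$ccr, 4))
  cat(sprintf("\nMCA: %.4f\n", x$mca))
  if (!is.null(x$per_level)) { cat("\n"); print(x$per_level) }
  invisible(x)
}
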
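# Two-level evaluation: per-pixel segmentation metrics (accuracy,
# sensitivity, specificity, precision, Jaccard, Dice) with explicit
# undefined-value semantics, and patch-level classification obtained by
# tiling segmented outputs and calling a tile positive iff it contains any
# Neo pixel. `NA` is the package's representation of an undefined metric
# (zero denominator); undefined values are excluded from averages, never
# treated as 0 or 1.

#' Segment a patch into Neo / NotNeo pixels
#'
#' Per-pixel argmax of the class probabilities; a pixel is Neo iff its Neo
#' probability strictly exceeds 0.5, so an exact tie is assigned NotNeo (the
#' conservative majority class).
#'
#' @param model a trained `neovaseg_model`.
#' @param patch height x width matrix of 8-bit intensities.
#' @return height x width integer mask, 1 = Neo, 0 = NotNeo.
#' @export
segment <- function(model, patch) {
  assert_that(inherits(model, "neovaseg_model"), "model must be a neovaseg_model")
  p <- forward(model, patch)
  matrix(as.integer(p[, , 2] > 0.5), nrow(patch), ncol(patch))
}

#' Tally a pixel-level confusion matrix
#'
#' Neo is the positive class: `tp` counts pixels labeled Neo in both masks,
#' `tn` pixels labeled NotNeo in both, `fp` predicted-Neo-only and `fn`
#' truth-Neo-only. Counts always sum to the number of pixels compared.
#'
#' @param prediction,truth aligned 0/1 masks (1 = Neo).
#' @return An object of class `confusion_counts`: list with `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion <- function(prediction, truth) {
  assert_that(all(dim(prediction) == dim(truth)),
              "prediction and truth masks must have identical dimensions")
  p <- as.vector(prediction) == 1
  t <- as.vector(truth) == 1
  confusion_counts(tp = sum(p & t), tn = sum(!p & !t),
                   fp = sum(p & !t), fn = sum(!p & t))
}

#' @rdname confusion
#' @param tp,tn,fp,fn non-negative counts.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  assert_that(all(c(tp, tn, fp, fn) >= 0), "counts must be non-negative")
  structure(list(tp = as.numeric(tp), tn = as.numeric(tn),
                 fp = as.numeric(fp), fn = as.numeric(fn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP %g  TN %g  FP %g  FN %g\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Derive the six evaluation metrics from confusion counts
#'
#' accuracy = (TP+TN)/total, sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), precision = TP/(TP+FP), Dice = 2TP/(2TP+FP+FN), Jaccard =
#' TP/(TP+FP+FN). A metric whose denominator is zero is undefined and
#' reported as `NA` — so on an all-negative image that is segmented perfectly,
#' accuracy and specificity are 1 while the other four are undefined; when
#' TP = FN = 0 but FP > 0, sensitivity is undefined while precision, Jaccard
#' and Dice are defined zeros. When defined, Dice = 2J/(1+J) and Dice is the
#' harmonic mean of precision and sensitivity.
#'
#' @param counts a [confusion_counts()].
#' @return An object of class `metrics_record`: one-row data.frame with
#'   columns `accuracy`, `sensitivity`, `specificity`, `precision`,
#'   `jaccard`, `dice`.
#' @export
compute_metrics <- function(counts) {
  assert_that(inherits(counts, "confusion_counts"), "counts must be confusion_counts")
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop("cannot compute metrics from zero evaluated units", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  rec <- data.frame(
    accuracy = ratio(counts$tp + counts$tn, total),
    sensitivity = ratio(counts$tp, counts$tp + counts$fn),
    specificity = ratio(counts$tn, counts$tn + counts$fp),
    precision = ratio(counts$tp, counts$tp + counts$fp),
    jaccard = ratio(counts$tp, counts$tp + counts$fp + counts$fn),
    dice = ratio(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn)
  )
  class(rec) <- c("metrics_record", class(rec))
  rec
}

#' Patch-level classification from segmentation masks
#'
#' Divides both masks into non-overlapping `tile_height` x `tile_width`
#' tiles (exact tiling required); a tile is positive iff it contains at least
#' one Neo pixel. Applied identically to prediction and truth, the tiles are
#' tallied as patch-level confusion counts, which is how a per-pixel
#' segmenter is compared against patch classifiers.
#'
#' @param prediction,truth aligned 0/1 masks with dimensions divisible by the
#'   tile size.
#' @param tile_height,tile_width tile size in pixels (default 200 x 296, an
#'   eighth of a 400 x 1184 patch).
#' @return A [confusion_counts()] over tiles.
#' @export
patch_classify <- function(prediction, truth, tile_height = 200L, tile_width = 296L) {
  assert_that(all(dim(prediction) == dim(truth)),
              "prediction and truth masks must have identical dimensions")
  grid <- patch_grid(tile_height, tile_width, nrow(truth), ncol(truth), mode = "exact")
  pt <- split_patches(prediction, grid)
  tt <- split_patches(truth, grid)
  p <- vapply(pt, function(m) any(m == 1), logical(1))
  t <- vapply(tt, function(m) any(m == 1), logical(1))
  confusion_counts(tp = sum(p & t), tn = sum(!p & !t),
                   fp = sum(p & !t), fn = sum(!p & t))
}

#' Aggregate per-image metrics into report averages
#'
#' Each average is the arithmetic mean over the images where that metric is
#' defined: `NA` (undefined) entries are excluded — never imputed as 0 or 1 —
#' while defined zeros are included. A metric undefined in every record has
#' an undefined average.
#'
#' @param records a list of [compute_metrics()] records, or a data.frame with
#'   the six metric columns.
#' @return One-row data.frame of per-metric averages (`NA` where undefined
#'   everywhere).
#' @export
aggregate_report <- function(records) {
  if (is.data.frame(records)) df <- records
  else {
    assert_that(length(records) > 0, "records must be non-empty")
    df <- do.call(rbind, lapply(records, as.data.frame))
  }
  cols <- c("accuracy", "sensitivity", "specificity", "precision", "jaccard", "dice")
  out <- lapply(cols, function(m) {
    v <- df[[m]][!is.na(df[[m]])]
    if (length(v) == 0) NA_real_ else mean(v)
  })
  names(out) <- cols
  as.data.frame(out)
}

#' Evaluate predicted masks against ground truth
#'
#' Computes per-image segmentation metrics, their defined-only averages, and
#' pooled patch-level classification metrics (tiles from all images tallied
#' into one confusion matrix before deriving metrics, so a report over fifty
#' 400 x 1184 patches classifies 400 tiles of 200 x 296).
#'
#' @param predictions,truths aligned lists of 0/1 masks.
#' @param tile_height,tile_width tile size for patch-level classification.
#' @return An object of class `evaluation_report`: list with `per_image`
#'   (data.frame, one row per mask pair), `segmentation_average`,
#'   `patch_confusion` ([confusion_counts()] over all tiles) and
#'   `patch_classification_average`.
#' @export
evaluate_masks <- function(predictions, truths, tile_height = 200L, tile_width = 296L) {
  assert_that(length(predictions) == length(truths) && length(truths) > 0,
              "predictions and truths must be non-empty aligned lists")
  per <- vector("list", length(truths))
  tile_counts <- confusion_counts(0, 0, 0, 0)
  for (i in seq_along(truths)) {
    per[[i]] <- compute_metrics(confusion(predictions[[i]], truths[[i]]))
    tc <- patch_classify(predictions[[i]], truths[[i]], tile_height, tile_width)
    tile_counts <- confusion_counts(tile_counts$tp + tc$tp, tile_counts$tn + tc$tn,
                                    tile_counts$fp + tc$fp, tile_counts$fn + tc$fn)
  }
  per_image <- do.call(rbind, lapply(per, as.data.frame))
  per_image <- cbind(image = seq_len(nrow(per_image)), per_image)
  structure(list(per_image = per_image,
                 segmentation_average = aggregate_report(per_image),
                 patch_confusion = tile_counts,
                 patch_classification_average = compute_metrics(tile_counts)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation report over %d images\n", nrow(x$per_image)))
  cat("segmentation averages (defined images only):\n")
  print(round_half_up(x$segmentation_average, 4))
  cat("patch classification (pooled tiles):\n")
  print(round_half_up(x$patch_classification_average[
    , c("accuracy", "sensitivity", "specificity", "precision")], 4))
  invisible(x)
}

#' Write an evaluation report as comma-separated text
#'
#' Mirrors the standard report layout: one row per image with the six
#' metrics rounded half-up to 4 decimals (empty cells where undefined),
#' followed by the segmentation-average row and the patch-classification
#' row.
#'
#' @param report an [evaluate_masks()] report.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_report_csv <- function(report, path) {
  fmt <- function(df) {
    df <- round_half_up(as.data.frame(df), 4)
    df
  }
  per <- fmt(report$per_image[, -1])
  per <- cbind(image = as.character(report$per_image$image), per)
  seg <- cbind(image = "segmentation_average", fmt(report$segmentation_average))
  pc <- fmt(report$patch_classification_average)
  pc$jaccard <- NA_real_; pc$dice <- NA_real_  # not reported at patch level
  pc <- cbind(image = "patch_classification_average", pc)
  utils::write.csv(rbind(per, seg, pc), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Reference 50-patch clinical evaluation metrics
#'
#' A published per-image metrics table from a 50-test-patch clinical fundus
#' evaluation of this architecture, shipped as a plain-text regression
#' fixture. Undefined metrics (zero denominators on all-negative patches)
#' are `NA`. Useful for checking the metric identities (Dice = 2J/(1+J),
#' Dice as the harmonic mean of precision and sensitivity, all at 4-decimal
#' printed precision) and the defined-only averaging rule.
#'
#' @return data.frame with columns `image` and the six metrics, 50 rows.
#' @export
reference_segmentation_metrics <- function() {
  path <- system.file("extdata", "reference_segmentation_metrics.tsv",
                      package = "neovaseg", mustWork = TRUE)
  utils::read.delim(path, na.strings = "-")
}
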
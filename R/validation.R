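# Pixel-level scoring of predicted canopy masks against labeled truth:
# precision = TP / (TP + FP), F1 = TP / (TP + (FP + FN)/2).

new_mask_score <- function(tp, fp, fn) {
  precision_defined <- (tp + fp) > 0
  f1_defined <- (tp + (fp + fn) / 2) > 0
  recall_defined <- (tp + fn) > 0
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = if (precision_defined) tp / (tp + fp) else NA_real_,
    recall = if (recall_defined) tp / (tp + fn) else NA_real_,
    f1 = if (f1_defined) tp / (tp + (fp + fn) / 2) else NA_real_,
    precision_defined = precision_defined,
    recall_defined = recall_defined,
    f1_defined = f1_defined),
    class = "mask_score")
}

#' @export
print.mask_score <- function(x, ...) {
  cat("mask_score: tp ", x$tp, ", fp ", x$fp, ", fn ", x$fn,
      "; precision ", format(x$precision), ", recall ", format(x$recall),
      ", f1 ", format(x$f1), "\n", sep = "")
  invisible(x)
}

#' Score a predicted canopy mask against a labeled truth mask
#'
#' Counts pixel-level true positives, false positives and false negatives
#' (nodata pixels of either mask excluded) and computes precision
#' `TP/(TP+FP)` and F1 `TP/(TP + (FP+FN)/2)`; recall `TP/(TP+FN)` is carried
#' as a bonus column. Undefined denominators are flagged (`*_defined` fields)
#' and reported as `NA`, never silently zeroed.
#'
#' @param pred,truth [canopy_mask()] objects of identical shape.
#' @return a `mask_score`.
#' @export
score_segmentation <- function(pred, truth) {
  stopifnot(inherits(pred, "canopy_mask"), inherits(truth, "canopy_mask"))
  if (!identical(dim(pred$mask), dim(truth$mask)))
    stop("shape mismatch between predicted and truth masks")
  keep <- !(pred$nodata_mask | truth$nodata_mask)
  p <- pred$mask[keep]; t <- truth$mask[keep]
  tp <- sum(p == 1L & t == 1L)
  fp <- sum(p == 1L & t == 0L)
  fn <- sum(p == 0L & t == 1L)
  s <- new_mask_score(tp, fp, fn)
  if (!s$f1_defined)
    warning("no positive pixels in prediction or truth: score undefined")
  s
}

#' Score labeled sample windows against a predicted mask
#'
#' Emulates validation against hand-labeled patches: each sample is a window
#' of the predicted mask paired with a truth patch of the same size. Returns
#' per-sample scores and a micro-pooled score over the summed TP/FP/FN.
#'
#' @param pred a [canopy_mask()] covering the full raster.
#' @param samples list of samples, each a list with `window` (half-open
#'   0-based `c(r0, r1, c0, c1)`) and `truth` (binary matrix of shape
#'   `(r1 - r0) x (c1 - c0)`, or a [canopy_mask()] of that shape).
#' @return list with `per_sample` (list of `mask_score`) and `pooled` (one
#'   `mask_score` over summed counts).
#' @export
score_samples <- function(pred, samples) {
  stopifnot(inherits(pred, "canopy_mask"))
  if (length(samples) == 0L) stop("empty sample list")
  nr <- nrow(pred$mask); nc <- ncol(pred$mask)
  per <- lapply(samples, function(s) {
    w <- as.integer(s$window)
    if (length(w) != 4L || w[1L] < 0L || w[3L] < 0L || w[2L] > nr ||
        w[4L] > nc || w[2L] <= w[1L] || w[4L] <= w[3L])
      stop("sample window outside raster or empty: ",
           paste(w, collapse = ", "))
    tr <- if (inherits(s$truth, "canopy_mask")) s$truth$mask else s$truth
    tr <- matrix(as.integer(tr), nrow(tr), ncol(tr))
    if (!identical(dim(tr), c(w[2L] - w[1L], w[4L] - w[3L])))
      stop("truth patch shape does not match its window")
    sub_pred <- canopy_mask(
      pred$mask[(w[1L] + 1L):w[2L], (w[3L] + 1L):w[4L], drop = FALSE],
      pred$nodata_mask[(w[1L] + 1L):w[2L], (w[3L] + 1L):w[4L], drop = FALSE])
    sub_truth <- canopy_mask(tr, sub_pred$nodata_mask)
    suppressWarnings(score_segmentation(sub_pred, sub_truth))
  })
  tp <- sum(vapply(per, `[[`, integer(1L), "tp"))
  fp <- sum(vapply(per, `[[`, integer(1L), "fp"))
  fn <- sum(vapply(per, `[[`, integer(1L), "fn"))
  list(per_sample = per, pooled = new_mask_score(tp, fp, fn))
}

#' Export scores as a table
#'
#' One row per parcel/sample with F1, precision and recall columns.
#'
#' @param scores named list of `mask_score` objects.
#' @return data frame `name, f1, precision, recall, tp, fp, fn`.
#' @export
scores_to_table <- function(scores) {
  do.call(rbind, lapply(names(scores), function(nm) {
    s <- scores[[nm]]
    data.frame(name = nm, f1 = s$f1, precision = s$precision,
               recall = s$recall, tp = s$tp, fp = s$fp, fn = s$fn)
  }))
}
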
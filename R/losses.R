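# Reference (pure R) implementations of the training objectives. The C++
# training engine computes the same quantities with gradients; these versions
# are the documented module surface and serve as an independent cross-check
# in the tests.

# normalise a batch argument (matrix, H x W x N array, or list of matrices)
# to a list of matrices
as_batch <- function(x) {
  if (is.list(x)) return(x)
  if (is.matrix(x)) return(list(x))
  if (is.array(x) && length(dim(x)) == 3)
    return(lapply(seq_len(dim(x)[3]), function(i) x[, , i]))
  stop("expected a matrix, 3D array, or list of matrices")
}

#' Soft Dice coefficient
#'
#' `(2 * sum(pred * truth) + smooth) / (sum(pred) + sum(truth) + smooth)`.
#' With binary `pred` and `smooth -> 0` this is the standard overlap Dice
#' `2|X n Y| / (|X| + |Y|)`, bounded in \[0, 1\]. The smoothing constant keeps
#' the ratio defined when both masks are empty during training.
#'
#' @param pred numeric matrix/array of probabilities in \[0, 1\].
#' @param truth binary matrix/array of the same shape.
#' @param smooth small positive stabiliser.
#' @return scalar in \[0, 1\].
#' @export
soft_dice <- function(pred, truth, smooth = 1e-6) {
  stopifnot(all(dim(pred) == dim(truth)))
  (2 * sum(pred * truth) + smooth) / (sum(pred) + sum(truth) + smooth)
}

new_loss_report <- function(total, per_term) {
  structure(list(total = total, per_term = per_term), class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("<loss_report total = %.6f>\n", x$total))
  for (nm in names(x$per_term))
    cat(sprintf("  %-14s %.6f\n", nm, x$per_term[[nm]]))
  invisible(x)
}

#' Single-task segmentation loss
#'
#' The negated batch-mean Dice of one organ: `-(1/N) * sum_i Dice_i`.
#' Perfect predictions give -1.
#'
#' @param preds,truths batches (matrix, 3D array, or list of matrices) of
#'   predictions and binary ground truth for one organ.
#' @param smooth Dice stabiliser.
#' @return a `"loss_report"` with `total` and `per_term = c(dice = ...)`.
#' @export
loss_stl <- function(preds, truths, smooth = 1e-6) {
  p <- as_batch(preds); t <- as_batch(truths)
  if (length(p) == 0) stop("empty batch")
  stopifnot(length(p) == length(t))
  d <- mapply(soft_dice, p, t, MoreArgs = list(smooth = smooth))
  new_loss_report(-mean(d), c(dice = mean(d)))
}

#' Joint spatially-correlated organ segmentation loss
#'
#' One Dice term per organ head, summed per sample and averaged over the
#' batch: `-(1/N) * sum_i (Dice_lung + Dice_heart + Dice_cord)_i`. Perfect
#' predictions give -3.
#'
#' @param preds,truths named lists (`lung`, `heart`, `cord`) of batches.
#' @param smooth Dice stabiliser.
#' @return a `"loss_report"`; `per_term` holds the three batch-mean Dice
#'   values, whose negated sum equals `total`.
#' @export
loss_scos <- function(preds, truths, smooth = 1e-6) {
  if (!all(ORGANS %in% names(preds)) || !all(ORGANS %in% names(truths)))
    stop("preds and truths must have heads ", paste(ORGANS, collapse = ", "))
  per <- numeric(0)
  for (org in ORGANS) {
    r <- loss_stl(preds[[org]], truths[[org]], smooth)
    per[paste0("dice_", org)] <- r$per_term[["dice"]]
  }
  new_loss_report(-sum(per), per)
}

#' Distance-map regression loss
#'
#' Sum of squared errors over pixels, `sum_x (g(x) - p(x))^2`, for one map
#' pair; for a batch, the per-image sums are averaged.
#'
#' @param pred_map,truth_map predicted and ground-truth distance maps
#'   (matrix, 3D array, or list).
#' @return non-negative scalar.
#' @export
loss_distance <- function(pred_map, truth_map) {
  p <- as_batch(pred_map); g <- as_batch(truth_map)
  stopifnot(length(p) == length(g))
  mean(mapply(function(a, b) sum((a - b)^2), g, p))
}

#' Multi-task losses with auxiliary shape heads
#'
#' `loss_tasks1` adds a distance-map regression term to the three-organ
#' segmentation loss; `loss_tasks2` additionally adds per-organ contour Dice
#' terms. Totals are plain unweighted sums of the constituent terms.
#'
#' @param seg_preds,seg_truths named organ lists of segmentation batches.
#' @param dist_pred,dist_truth distance-map batches.
#' @param contour_preds,contour_truths named organ lists of contour batches
#'   (`loss_tasks2` only).
#' @param smooth Dice stabiliser.
#' @return a `"loss_report"`; `per_term` keys are `dice_<organ>`, `distance`,
#'   and for `loss_tasks2` also `contour_<organ>`.
#' @export
loss_tasks1 <- function(seg_preds, seg_truths, dist_pred, dist_truth,
                        smooth = 1e-6) {
  seg <- loss_scos(seg_preds, seg_truths, smooth)
  per <- c(seg$per_term, distance = loss_distance(dist_pred, dist_truth))
  new_loss_report(seg$total + per[["distance"]], per)
}

#' @rdname loss_tasks1
#' @export
loss_tasks2 <- function(seg_preds, seg_truths, contour_preds, contour_truths,
                        dist_pred, dist_truth, smooth = 1e-6) {
  seg <- loss_scos(seg_preds, seg_truths, smooth)
  if (!all(ORGANS %in% names(contour_preds)))
    stop("contour_preds must have heads ", paste(ORGANS, collapse = ", "))
  cper <- numeric(0)
  for (org in ORGANS) {
    r <- loss_stl(contour_preds[[org]], contour_truths[[org]], smooth)
    cper[paste0("contour_", org)] <- r$per_term[["dice"]]
  }
  per <- c(seg$per_term, cper,
           distance = loss_distance(dist_pred, dist_truth))
  new_loss_report(seg$total - sum(cper) + per[["distance"]], per)
}
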
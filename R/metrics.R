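#' Threshold a probability map into a binary mask
#'
#' Pixels with probability greater than or equal to the threshold become
#' foreground (boundary inclusive). Idempotent on binary input.
#'
#' @param prob numeric matrix/array in \[0, 1\].
#' @param threshold scalar in (0, 1).
#' @return 0/1 integer matrix/array of the same shape.
#' @export
binarize <- function(prob, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  out <- (prob >= threshold) * 1L
  dim(out) <- dim(prob)
  out
}

# contour (surface) extraction: 2D uses the 8-connected edge shared with
# contour_map(); 3D uses the analogous 3x3x3 (26-neighbourhood) erosion.
# Outside the array counts as background.
mask_contour <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2) return(contour_map(mask))
  m <- mask != 0
  p <- array(FALSE, d + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  er <- m
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    er <- er & p[(2 + di):(d[1] + 1 + di), (2 + dj):(d[2] + 1 + dj),
                 (2 + dk):(d[3] + 1 + dk)]
  }
  (m & !er) * 1L
}

contour_coords <- function(mask) {
  which(mask_contour(mask) != 0, arr.ind = TRUE)
}

#' Directed nearest-neighbour distances between contour pixel sets
#'
#' For every point of `A`, the minimum Euclidean distance to any point of
#' `B`, optionally scaled by per-axis pixel spacing. The result has exactly
#' `nrow(A)` entries.
#'
#' @param A,B coordinate matrices (rows = points, columns = axes), e.g. from
#'   `which(..., arr.ind = TRUE)` on a contour mask.
#' @param spacing per-axis physical spacing; `NULL` means unit pixels.
#' @return numeric vector of length `nrow(A)`.
#' @export
directed_distances <- function(A, B, spacing = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(B) == 0) stop("B must be non-empty; the caller handles the inf convention")
  if (nrow(A) == 0) return(numeric(0))
  if (is.null(spacing)) spacing <- rep(1, ncol(A))
  .nn_min_dist(A, B, as.numeric(spacing))
}

# pooled directed surface distances of two masks, or NULL when X is empty
pooled_surface_distances <- function(X, Y, spacing) {
  cY <- contour_coords(Y)
  if (nrow(cY) == 0) stop("ground truth mask is empty: metric undefined")
  cX <- contour_coords(X)
  if (nrow(cX) == 0) return(NULL)
  if (is.null(spacing)) spacing <- rep(1, ncol(cX))
  list(xy = .nn_min_dist(cX, cY, as.numeric(spacing)),
       yx = .nn_min_dist(cY, cX, as.numeric(spacing)),
       nX = nrow(cX), nY = nrow(cY))
}

#' Surface-distance metrics between a predicted and a ground-truth mask
#'
#' All three metrics pool the two directed nearest-neighbour distance sets
#' computed on contour (2D) or surface (3D) pixels: `max_hd` is the maximum
#' (the symmetric Hausdorff distance), `hd95` the 95th percentile (linear
#' interpolation between order statistics), and `asd` the average
#' `(sum d(x, dY) + sum d(y, dX)) / (nX + nY)`. An empty prediction `X`
#' against a non-empty truth `Y` returns `Inf` (total recognition failure);
#' an empty truth is an error, such cases are excluded from evaluation.
#'
#' @param X predicted binary mask (matrix or 3D array).
#' @param Y ground-truth binary mask, same shape, non-empty.
#' @param spacing per-axis spacing (mm); `NULL` reports in pixels.
#' @return scalar distance, possibly `Inf`.
#' @export
max_hd <- function(X, Y, spacing = NULL) {
  d <- pooled_surface_distances(X, Y, spacing)
  if (is.null(d)) return(Inf)
  max(d$xy, d$yx)
}

#' @rdname max_hd
#' @export
hd95 <- function(X, Y, spacing = NULL) {
  d <- pooled_surface_distances(X, Y, spacing)
  if (is.null(d)) return(Inf)
  quantile(c(d$xy, d$yx), 0.95, names = FALSE, type = 7)
}

#' @rdname max_hd
#' @export
asd <- function(X, Y, spacing = NULL) {
  d <- pooled_surface_distances(X, Y, spacing)
  if (is.null(d)) return(Inf)
  (sum(d$xy) + sum(d$yx)) / (d$nX + d$nY)
}

# hard-mask overlap Dice; empty prediction against non-empty truth gives 0
hard_dice <- function(X, Y) {
  sx <- sum(X != 0); sy <- sum(Y != 0)
  if (sx + sy == 0) return(NA_real_)
  2 * sum(X != 0 & Y != 0) / (sx + sy)
}

#' Count total recognition failures
#'
#' The number of evaluation records whose average surface distance is
#' infinite, i.e. cases where the model predicted nothing for an organ that
#' is present.
#'
#' @param records a data frame from [evaluate_masks()] (or any data frame
#'   with an `asd` column).
#' @return integer count.
#' @export
n_inf <- function(records) {
  if (NROW(records) == 0) return(0L)
  sum(is.infinite(records$asd))
}

#' Keep only the largest 3D connected component
#'
#' Labels the foreground with 26-connectivity and zeroes every voxel outside
#' the largest component. Ties between equally large components are broken
#' deterministically in favour of the component whose smallest linear voxel
#' index comes first. Empty input is returned unchanged. A matrix input is
#' treated as a single-slice volume (8-connectivity).
#'
#' @param mask binary 3D array (or matrix).
#' @return mask of the same shape with only the largest component retained.
#' @export
largest_cc_3d <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2) d <- c(d, 1L)
  lab <- .label_cc(as.integer(mask != 0), d[1], d[2], d[3], 26L)
  ncomp <- attr(lab, "n_components")
  if (ncomp <= 1) return(mask)
  sizes <- tabulate(lab, nbins = ncomp)
  keep <- which.max(sizes)  # first maximum = first-encountered component
  out <- (lab == keep) * 1L
  dim(out) <- dim(mask)
  out
}

evaluate_case <- function(pred_masks, truth_masks, case_id, spacing,
                          postprocess, threshold) {
  rows <- list()
  for (org in names(truth_masks)) {
    Y <- truth_masks[[org]]
    if (sum(Y != 0) == 0) next  # truth absent: excluded from evaluation
    X <- pred_masks[[org]]
    if (is.null(X)) stop("missing prediction for organ '", org, "'")
    if (!all(dim(X) == dim(Y))) stop("prediction/truth shape mismatch")
    if (any(X > 0 & X < 1)) X <- binarize(X, threshold)
    if (postprocess && sum(X != 0) > 0) X <- largest_cc_3d(X)
    if (sum(X != 0) == 0) {
      rows[[org]] <- data.frame(case_id = case_id, organ = org, dice = 0,
                                max_hd = Inf, hd95 = Inf, asd = Inf,
                                is_inf = TRUE, stringsAsFactors = FALSE)
    } else {
      d <- pooled_surface_distances(X, Y, spacing)
      pooled <- c(d$xy, d$yx)
      rows[[org]] <- data.frame(
        case_id = case_id, organ = org, dice = hard_dice(X, Y),
        max_hd = max(pooled),
        hd95 = quantile(pooled, 0.95, names = FALSE, type = 7),
        asd = (sum(d$xy) + sum(d$yx)) / (d$nX + d$nY),
        is_inf = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Evaluate predicted masks against ground truth
#'
#' Computes per-case, per-organ Dice, maximum and 95th-percentile Hausdorff
#' distance, and average surface distance, with the infinity convention for
#' empty predictions. In `"2d"` mode each case is one slice (masks are
#' matrices); in `"3d"` mode each case is one volume (masks are 3D arrays)
#' and the largest-connected-component post-processing is applied by default,
#' as is usual in clinical practice. Organs whose ground truth is empty in a
#' case are excluded rather than scored.
#'
#' @param pred,truth lists of cases; each case is a named list of per-organ
#'   binary masks (predictions may also be probability maps, which are
#'   thresholded at `threshold`).
#' @param mode `"2d"` or `"3d"`.
#' @param spacing per-axis spacing in mm (`NULL` = pixels).
#' @param postprocess apply [largest_cc_3d()] to each predicted organ mask.
#' @param threshold binarisation threshold for probability inputs.
#' @param case_ids optional case identifiers.
#' @return data frame with columns `case_id`, `organ`, `dice`, `max_hd`,
#'   `hd95`, `asd`, `is_inf`.
#' @export
evaluate_masks <- function(pred, truth, mode = c("2d", "3d"), spacing = NULL,
                           postprocess = (mode == "3d"), threshold = 0.5,
                           case_ids = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(pred) == length(truth))
  if (is.null(case_ids))
    case_ids <- sprintf("%s%04d", if (mode == "2d") "slice" else "vol",
                        seq_along(pred))
  postprocess <- isTRUE(postprocess)
  out <- vector("list", length(pred))
  for (i in seq_along(pred)) {
    nd <- if (mode == "2d") 2L else 3L
    if (length(dim(truth[[i]][[1]])) != nd)
      stop("mask dimensionality does not match mode")
    if (!is.null(spacing) && length(spacing) != nd)
      stop("spacing length does not match mode")
    out[[i]] <- evaluate_case(pred[[i]], truth[[i]], case_ids[i], spacing,
                              postprocess, threshold)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quartile summary of a metric
#'
#' Quartiles (linear interpolation between order statistics), IQR, and mean
#' are computed over the finite values only; infinite values are counted
#' separately as `n_inf`. If no finite value exists the quartiles are `NA`.
#'
#' @param values numeric vector, possibly containing `Inf`.
#' @return an object of class `"summary_stats"`: list with `q1`, `median`,
#'   `q3`, `iqr`, `mean`, `n`, `n_inf`.
#' @export
summarize_metric <- function(values) {
  values <- values[!is.na(values)]
  fin <- values[is.finite(values)]
  if (length(fin) == 0) {
    qs <- c(NA_real_, NA_real_, NA_real_)
    mn <- NA_real_
  } else {
    qs <- quantile(fin, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    mn <- mean(fin)
  }
  structure(list(q1 = qs[1], median = qs[2], q3 = qs[3], iqr = qs[3] - qs[1],
                 mean = mn, n = length(values),
                 n_inf = sum(is.infinite(values))),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "<summary_stats n=%d n_inf=%d  Q1=%.4g median=%.4g Q3=%.4g IQR=%.4g mean=%.4g>\n",
    x$n, x$n_inf, x$q1, x$median, x$q3, x$iqr, x$mean))
  invisible(x)
}

#' Summarise evaluation records by organ and metric
#'
#' @param records data frame from [evaluate_masks()].
#' @return data frame with one row per (organ, metric) and columns `q1`,
#'   `median`, `q3`, `iqr`, `mean`, `n`, `n_inf`.
#' @export
summarize_records <- function(records) {
  mets <- c("dice", "max_hd", "hd95", "asd")
  rows <- list()
  for (org in unique(records$organ)) {
    sub <- records[records$organ == org, ]
    for (m in mets) {
      s <- summarize_metric(sub[[m]])
      rows[[paste(org, m)]] <- data.frame(
        organ = org, metric = m, q1 = s$q1, median = s$median, q3 = s$q3,
        iqr = s$iqr, mean = s$mean, n = s$n, n_inf = s$n_inf,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write a quartile summary of evaluation records as JSON
#'
#' One object per (organ, metric) with the [summarize_metric()] fields;
#' requires the jsonlite package.
#'
#' @param records data frame from [evaluate_masks()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_summary_json <- function(records, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_summary_json() needs the jsonlite package")
  s <- summarize_records(records)
  out <- list()
  for (i in seq_len(nrow(s)))
    out[[paste(s$organ[i], s$metric[i], sep = "_")]] <-
      as.list(s[i, !(names(s) %in% c("organ", "metric"))])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write evaluation records to CSV
#'
#' One row per (case, organ) record; infinite distances are written as `Inf`.
#'
#' @param records data frame from [evaluate_masks()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_metrics_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
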
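#' Intensity window specification
#'
#' Linear mapping of a Hounsfield-unit interval to a display/network range.
#' The default reproduces the soft-tissue window used for training data:
#' -135..215 HU mapped to 0..255.
#'
#' @param hu_min,hu_max input window bounds (HU), `hu_max > hu_min`.
#' @param out_min,out_max output bounds, `out_max > out_min`.
#' @return an object of class `"window_spec"`.
#' @export
window_spec <- function(hu_min = -135, hu_max = 215, out_min = 0,
                        out_max = 255) {
  stopifnot(hu_max > hu_min, out_max > out_min)
  structure(list(hu_min = hu_min, hu_max = hu_max, out_min = out_min,
                 out_max = out_max), class = "window_spec")
}

#' Window CT intensities
#'
#' Values are clamped to `[hu_min, hu_max]` and then mapped linearly onto
#' `[out_min, out_max]`. Clamping means air (-1000 HU) maps exactly to
#' `out_min` rather than below it. The map is monotone non-decreasing.
#'
#' @param image numeric matrix/array of HU values.
#' @param spec a [window_spec()].
#' @return same shape as `image`, values in `[out_min, out_max]`.
#' @export
#' @examples
#' window_intensity(matrix(c(-135, 40, 215), 1), window_spec())
window_intensity <- function(image, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  v <- pmin(pmax(image, spec$hu_min), spec$hu_max)
  spec$out_min + (v - spec$hu_min) *
    (spec$out_max - spec$out_min) / (spec$hu_max - spec$hu_min)
}

#' Crop rows symmetrically from the top and bottom of an image
#'
#' Reproduces the preprocessing step that trims a 512x512 CT slice to
#' 512 columns x 256 rows by dropping 128 rows from each side. Columns are
#' untouched; the caller crops masks identically.
#'
#' @param image matrix.
#' @param n_drop_each_side rows removed from each of top and bottom.
#' @return the cropped matrix.
#' @export
crop_rows <- function(image, n_drop_each_side) {
  n <- as.integer(n_drop_each_side)
  stopifnot(n >= 0)
  if (nrow(image) < 2 * n + 1)
    stop("image has too few rows for the requested crop")
  if (n == 0) return(image)
  image[(n + 1):(nrow(image) - n), , drop = FALSE]
}

rotate_matrix_bilinear <- function(m, angle_deg, fill) {
  if (angle_deg == 0) return(m)
  .rot_resample(m, angle_deg, fill, TRUE)
}

rotate_matrix_nn <- function(m, angle_deg, fill = 0) {
  if (angle_deg == 0) return(m)
  storage.mode(m) <- "double"
  out <- .rot_resample(m, angle_deg, fill, FALSE)
  storage.mode(out) <- "integer"
  out
}

#' Rotate a labelled slice by image resampling
#'
#' The image is rotated about the image centre with bilinear interpolation;
#' each mask with nearest-neighbour interpolation (so disjoint labels stay
#' disjoint and no new label values appear). This is the augmentation-style
#' rotation applied to training samples; it is distinct from the phantom's
#' analytic rotation, which produces exact masks.
#'
#' @param slice a `"labeled_slice"`.
#' @param angle_deg rotation angle in degrees (same sign convention as the
#'   phantom's analytic rotation).
#' @param fill intensity for pixels rotated in from outside the image; the
#'   default uses the image minimum, i.e. the (possibly windowed) background
#'   air value.
#' @return a `"labeled_slice"` with `angle_deg` accumulated.
#' @export
rotate_sample <- function(slice, angle_deg, fill = NULL) {
  stopifnot(inherits(slice, "labeled_slice"))
  if (is.null(fill)) fill <- min(slice$image)
  img <- rotate_matrix_bilinear(slice$image, angle_deg, fill)
  masks <- lapply(slice$masks, rotate_matrix_nn, angle_deg = angle_deg)
  new_labeled_slice(img, masks, slice$angle_deg + angle_deg, slice$case_id,
                    slice$slice_index)
}

#' Random rotation augmentation
#'
#' Draws an angle uniformly from `range_deg` (using the current R
#' random-number stream) and applies [rotate_sample()]. Intended for online,
#' per-epoch use on training samples.
#'
#' @param slice a `"labeled_slice"`.
#' @param range_deg closed interval of angles in degrees.
#' @param fill see [rotate_sample()].
#' @return the rotated slice.
#' @export
random_rotation_augment <- function(slice, range_deg = c(-30, 30),
                                    fill = NULL) {
  stopifnot(length(range_deg) == 2, range_deg[1] <= range_deg[2])
  rotate_sample(slice, runif(1, range_deg[1], range_deg[2]), fill = fill)
}
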
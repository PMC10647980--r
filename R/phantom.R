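#' Configuration for the synthetic thorax phantom
#'
#' The phantom stands in for transverse thoracic CT slices: an elliptical body
#' outline filled with soft tissue, two air-filled lung fields with a concave
#' medial border, a heart placed between the lungs, and a small spinal cord
#' sitting in the hole of a bright posterior vertebral ring. Organ positions
#' are spatially correlated: the heart centre is tied to the midpoint of the
#' two lung centres, and the cord sits on the posterior midline. All shapes
#' are analytic (ellipses/discs), rotated at the parameter level before
#' rasterisation, so ground-truth masks are exact at any angle.
#'
#' @param image_height,image_width slice size in pixels.
#' @param lung_size_range range of the lung semi-axis (columns), as a fraction
#'   of image width; the vertical semi-axis is 1.35 times larger.
#' @param heart_size_range range of the heart semi-axis (columns), fraction of
#'   image width; the vertical semi-axis is 0.85 times smaller.
#' @param cord_radius_range range of the spinal cord disc radius, in pixels.
#' @param jitter_scale standard deviation (pixels) of Gaussian perturbations
#'   applied to organ centres.
#' @param noise_sd standard deviation of additive Gaussian intensity noise, in
#'   Hounsfield-like units, added after rasterisation.
#' @param intensity_levels named numeric vector of HU-like fill values with
#'   entries `background`, `body`, `lung`, `heart`, `cord`, `csf`,
#'   `vertebra`. Defaults approximate CT: air -1000, soft tissue/heart 40,
#'   lung -700, cord 30 inside a cerebrospinal-fluid gap at 5, vertebral
#'   bone 400, so that the -135..215 HU display window is meaningful. Note
#'   heart and body share one level on purpose: the heart is only
#'   identifiable from its position between the lungs.
#' @param rotation_range_deg closed interval of in-plane rotation angles in
#'   degrees, inside \[-90, 90\].
#' @param seed integer seed for [generate_dataset()] / [generate_volume()];
#'   `NULL` leaves the R random-number stream untouched.
#'
#' @return an object of class `"phantom_config"`.
#' @export
#' @examples
#' cfg <- phantom_config(seed = 1)
#' sl <- generate_dataset(cfg, 1)[[1]]
#' range(sl$image)
phantom_config <- function(image_height = 64L, image_width = 64L,
                           lung_size_range = c(0.13, 0.17),
                           heart_size_range = c(0.10, 0.14),
                           cord_radius_range = c(1.8, 2.6),
                           jitter_scale = 1.5, noise_sd = 15,
                           intensity_levels = c(background = -1000, body = 40,
                                                lung = -700, heart = 40,
                                                cord = 30, csf = 5,
                                                vertebra = 400),
                           rotation_range_deg = c(-30, 30), seed = NULL) {
  cfg <- list(image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              lung_size_range = as.numeric(lung_size_range),
              heart_size_range = as.numeric(heart_size_range),
              cord_radius_range = as.numeric(cord_radius_range),
              jitter_scale = as.numeric(jitter_scale),
              noise_sd = as.numeric(noise_sd),
              intensity_levels = intensity_levels,
              rotation_range_deg = as.numeric(rotation_range_deg),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(cfg$image_height >= 16, cfg$image_width >= 16)
  rng_ok <- function(r) length(r) == 2 && all(r > 0) && r[2] >= r[1]
  if (!rng_ok(cfg$lung_size_range) || !rng_ok(cfg$heart_size_range) ||
      !rng_ok(cfg$cord_radius_range))
    stop("invalid config: all size ranges must be positive and ordered")
  if (cfg$jitter_scale < 0 || cfg$noise_sd < 0)
    stop("invalid config: jitter_scale and noise_sd must be non-negative")
  need <- c("background", "body", "lung", "heart", "cord", "csf", "vertebra")
  if (!all(need %in% names(cfg$intensity_levels)))
    stop("invalid config: intensity_levels must name ", paste(need, collapse = ", "))
  rr <- cfg$rotation_range_deg
  if (length(rr) != 2 || rr[1] > rr[2] || rr[1] < -90 || rr[2] > 90)
    stop("invalid config: rotation_range_deg must be an interval inside [-90, 90]")
  # geometric feasibility at the largest drawn sizes
  W <- cfg$image_width; H <- cfg$image_height
  # organs are intersected with the body outline when rasterised, so the
  # checks only need to rule out grossly infeasible geometry (organ centres
  # or whole organs escaping the body)
  a_body <- 0.44 * W; b_body <- 0.40 * H
  margin <- 2 * cfg$jitter_scale
  lung_a <- max(cfg$lung_size_range) * W
  if (0.21 * W + lung_a + margin > a_body)
    stop("invalid config: lungs do not fit inside the body outline")
  if (0.02 * H + 1.35 * lung_a + margin > b_body)
    stop("invalid config: lungs too tall for the body outline")
  if (max(cfg$heart_size_range) * W + margin > a_body)
    stop("invalid config: heart does not fit inside the body outline")
  if (0.28 * H + max(cfg$cord_radius_range) + 4.5 > b_body)
    stop("invalid config: vertebral ring does not fit inside the body outline")
  if (min(cfg$cord_radius_range) < 1)
    stop("invalid config: cord radius below 1 pixel gives empty masks")
  invisible(cfg)
}

# rotate points (x, y) by theta degrees about (cx, cy);
# x = column coordinate, y = row coordinate
rotate_xy <- function(x, y, theta_deg, cx, cy) {
  th <- theta_deg * pi / 180
  dx <- x - cx; dy <- y - cy
  list(x = cx + cos(th) * dx - sin(th) * dy,
       y = cy + sin(th) * dx + cos(th) * dy)
}

# rasterise a rotated ellipse: centre (cx, cy) in (col, row) coords,
# semi-axes a (cols), b (rows), orientation phi degrees
ellipse_mask <- function(H, W, cx, cy, a, b, phi_deg = 0) {
  ph <- phi_deg * pi / 180
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  dx <- xs - cx; dy <- ys - cy
  u <- cos(ph) * dx + sin(ph) * dy
  v <- -sin(ph) * dx + cos(ph) * dy
  (u / a)^2 + (v / b)^2 <= 1
}

disc_mask <- function(H, W, cx, cy, r) ellipse_mask(H, W, cx, cy, r, r)

# draw slice geometry (unrotated); sizes in pixels, centres in (col,row)
draw_geometry <- function(cfg) {
  W <- cfg$image_width; H <- cfg$image_height
  cc <- (W + 1) / 2; rc <- (H + 1) / 2
  j <- cfg$jitter_scale
  lung_a <- runif(2, cfg$lung_size_range[1], cfg$lung_size_range[2]) * W
  lung_cx <- cc + c(-1, 1) * 0.21 * W + rnorm(2, 0, j)
  lung_cy <- rc - 0.02 * H + rnorm(2, 0, j)
  heart_a <- runif(1, cfg$heart_size_range[1], cfg$heart_size_range[2]) * W
  # the heart centre is tied to the lung midpoint: this is the spatial
  # correlation the joint-learning setting is meant to exploit
  heart_cx <- mean(lung_cx) + rnorm(1, 0, j)
  heart_cy <- mean(lung_cy)
  cord_r <- runif(1, cfg$cord_radius_range[1], cfg$cord_radius_range[2])
  cord_cx <- cc + rnorm(1, 0, j / 2)
  cord_cy <- rc + 0.28 * H
  list(W = W, H = H, cc = cc, rc = rc,
       body_a = 0.44 * W, body_b = 0.40 * H,
       lung_a = lung_a, lung_b = 1.35 * lung_a,
       lung_cx = lung_cx, lung_cy = lung_cy,
       heart_a = heart_a, heart_b = 0.85 * heart_a,
       heart_cx = heart_cx, heart_cy = heart_cy,
       cord_r = cord_r, cord_cx = cord_cx, cord_cy = cord_cy,
       ring_in = cord_r + 1.5, ring_out = cord_r + 4.5)
}

# rasterise geometry at a given angle; scale factors shrink organs for the
# apical/basal slices of a volume (0 = organ absent)
raster_slice <- function(geom, cfg, angle_deg, lung_scale = 1,
                         heart_scale = 1, add_noise = TRUE) {
  H <- geom$H; W <- geom$W
  rot <- function(cx, cy) rotate_xy(cx, cy, angle_deg, geom$cc, geom$rc)
  lev <- cfg$intensity_levels

  body <- ellipse_mask(H, W, geom$cc, geom$rc, geom$body_a, geom$body_b,
                       angle_deg)
  lung_ell <- vector("list", 2)
  for (k in 1:2) {
    p <- rot(geom$lung_cx[k], geom$lung_cy[k])
    lung_ell[[k]] <- if (lung_scale > 0)
      ellipse_mask(H, W, p$x, p$y, geom$lung_a[k] * lung_scale,
                   geom$lung_b[k] * lung_scale, angle_deg)
    else matrix(FALSE, H, W)
  }
  hp <- rot(geom$heart_cx, geom$heart_cy)
  heart_ell <- if (heart_scale > 0)
    ellipse_mask(H, W, hp$x, hp$y, geom$heart_a * heart_scale,
                 geom$heart_b * heart_scale, angle_deg)
  else matrix(FALSE, H, W)
  # margin around the heart carves the lungs' concave medial border and
  # guarantees lung/heart disjointness
  heart_margin <- if (heart_scale > 0)
    ellipse_mask(H, W, hp$x, hp$y, geom$heart_a * heart_scale + 1,
                 geom$heart_b * heart_scale + 1, angle_deg)
  else matrix(FALSE, H, W)
  cp <- rot(geom$cord_cx, geom$cord_cy)
  cord <- disc_mask(H, W, cp$x, cp$y, geom$cord_r) & body
  ring_disc <- disc_mask(H, W, cp$x, cp$y, geom$ring_out)
  hole <- disc_mask(H, W, cp$x, cp$y, geom$ring_in)
  ring <- ring_disc & !hole

  lung <- (lung_ell[[1]] | lung_ell[[2]]) & !heart_margin & !ring_disc & body
  heart <- heart_ell & !ring_disc & !cord & body

  img <- matrix(lev[["background"]], H, W)
  img[body] <- lev[["body"]]
  img[lung] <- lev[["lung"]]
  img[heart] <- lev[["heart"]]
  img[ring] <- lev[["vertebra"]]
  img[hole & body] <- lev[["csf"]]  # cerebrospinal fluid fills the canal
  img[cord] <- lev[["cord"]]
  if (add_noise && cfg$noise_sd > 0)
    img <- img + matrix(rnorm(H * W, 0, cfg$noise_sd), H, W)
  list(image = img,
       masks = list(lung = lung * 1L, heart = heart * 1L, cord = cord * 1L))
}

new_labeled_slice <- function(image, masks, angle_deg, case_id, slice_index) {
  structure(list(image = image, masks = masks, angle_deg = angle_deg,
                 case_id = case_id, slice_index = as.integer(slice_index)),
            class = "labeled_slice")
}

#' Generate one labelled phantom slice
#'
#' Draws organ geometry (sizes, jittered centres) and a rotation angle from
#' the configured ranges using the current R random-number stream, then
#' rasterises the analytically rotated shapes. Masks are pairwise disjoint and
#' each organ is non-empty; the lung mask has exactly two connected
#' components.
#'
#' @param config a [phantom_config()].
#' @param case_id,slice_index identifiers stored on the slice.
#' @param angle_deg optional fixed rotation angle; `NULL` (default) draws
#'   uniformly from `config$rotation_range_deg`.
#' @return a `"labeled_slice"`: list with `image` (HU-like matrix), `masks`
#'   (named list of 0/1 matrices `lung`, `heart`, `cord`), `angle_deg`,
#'   `case_id`, `slice_index`.
#' @export
generate_slice <- function(config, case_id = "case0001", slice_index = 1L,
                           angle_deg = NULL) {
  validate_phantom_config(config)
  geom <- draw_geometry(config)
  if (is.null(angle_deg))
    angle_deg <- runif(1, config$rotation_range_deg[1],
                       config$rotation_range_deg[2])
  rs <- raster_slice(geom, config, angle_deg)
  if (any(vapply(rs$masks, sum, 0) == 0))
    stop("invalid config: an organ rasterised to an empty mask")
  new_labeled_slice(rs$image, rs$masks, angle_deg, case_id, slice_index)
}

#' Generate a dataset of independent phantom slices
#'
#' If `config$seed` is set, the R random-number stream is seeded first, so the
#' same configuration always regenerates a bit-identical dataset.
#'
#' @param config a [phantom_config()].
#' @param n_slices number of slices (>= 1).
#' @param rotated if `FALSE` every slice has `angle_deg = 0` (the training
#'   population, scanned in supine position); if `TRUE` angles are drawn
#'   uniformly from `config$rotation_range_deg` (the rotated test population).
#' @return list of [generate_slice()] results.
#' @export
generate_dataset <- function(config, n_slices, rotated = FALSE) {
  stopifnot(n_slices >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  lapply(seq_len(n_slices), function(i)
    generate_slice(config, case_id = sprintf("case%04d", i), slice_index = 1L,
                   angle_deg = if (rotated) NULL else 0))
}

#' Generate one coherent phantom volume
#'
#' One geometry draw is shared by all slices of the case; organ extent varies
#' smoothly along the slice axis via a sinusoidal profile, so the spinal cord
#' runs through every slice while lungs and heart occupy a contiguous central
#' run (the heart is absent from the first and last slices). A single rotation
#' angle is applied to the whole stack, mimicking a patient positioned at an
#' angle. Unlike [generate_slice()], apical/basal slices may legitimately have
#' empty lung or heart masks.
#'
#' @param config a [phantom_config()]; `config$seed` (when set) makes the
#'   volume reproducible.
#' @param n_slices number of slices (>= 2).
#' @param angle_deg rotation applied to every slice, degrees.
#' @param case_id identifier.
#' @param spacing voxel spacing `c(row, col, thickness)` in mm.
#' @return a `"labeled_volume"`: list with `slices` and `spacing`.
#' @export
generate_volume <- function(config, n_slices, angle_deg, case_id = "vol0001",
                            spacing = c(1, 1, 5)) {
  stopifnot(n_slices >= 2)
  validate_phantom_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  geom <- draw_geometry(config)
  slices <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    t <- (i - 1) / (n_slices - 1)
    heart_scale <- sin(pi * t)          # exactly 0 on first/last slice
    lung_scale <- sqrt(sin(pi * t))     # wider central run than the heart
    rs <- raster_slice(geom, config, angle_deg, lung_scale, heart_scale)
    slices[[i]] <- new_labeled_slice(rs$image, rs$masks, angle_deg, case_id, i)
  }
  structure(list(slices = slices, spacing = as.numeric(spacing)),
            class = "labeled_volume")
}

#' @export
print.labeled_slice <- function(x, ...) {
  cat(sprintf("<labeled_slice %s/%d  %dx%d  angle %.2f deg  organ px: %s>\n",
              x$case_id, x$slice_index, nrow(x$image), ncol(x$image),
              x$angle_deg,
              paste(sprintf("%s=%d", names(x$masks),
                            vapply(x$masks, sum, 0)), collapse = " ")))
  invisible(x)
}

#' @export
print.labeled_volume <- function(x, ...) {
  s1 <- x$slices[[1]]
  cat(sprintf("<labeled_volume %s  %d slices of %dx%d  angle %.2f deg  spacing %s mm>\n",
              s1$case_id, length(x$slices), nrow(s1$image), ncol(s1$image),
              s1$angle_deg, paste(x$spacing, collapse = "x")))
  invisible(x)
}

# stack a volume's images / per-organ masks into 3D arrays
volume_image_array <- function(volume) {
  simplify2array(lapply(volume$slices, `[[`, "image"))
}

volume_mask_array <- function(volume, organ) {
  simplify2array(lapply(volume$slices, function(s) s$masks[[organ]]))
}

#' Write a labelled volume as a NIfTI image/label pair
#'
#' The label volume uses integer codes 0 = background, 1 = lung, 2 = heart,
#' 3 = spinal cord.
#'
#' @param volume a [generate_volume()] result.
#' @param image_path,label_path output file paths (`.nii` or `.nii.gz`).
#' @return invisibly, the two paths.
#' @export
write_volume_nifti <- function(volume, image_path, label_path) {
  img <- volume_image_array(volume)
  lab <- array(0L, dim = dim(img))
  for (k in seq_along(ORGANS)) lab[volume_mask_array(volume, ORGANS[k]) == 1] <- k
  nim <- RNifti::asNifti(img)
  RNifti::pixdim(nim) <- volume$spacing
  nlab <- RNifti::asNifti(lab)
  RNifti::pixdim(nlab) <- volume$spacing
  RNifti::writeNifti(nim, image_path)
  RNifti::writeNifti(nlab, label_path)
  invisible(c(image_path, label_path))
}

#' Read a NIfTI image/label pair into a labelled volume
#'
#' Inverse of [write_volume_nifti()]; label codes as documented there.
#'
#' @param image_path,label_path files written by [write_volume_nifti()] or an
#'   equivalent external tool.
#' @return a `"labeled_volume"` (with `angle_deg = NA`, unknown).
#' @export
read_volume_nifti <- function(image_path, label_path) {
  img <- as.array(RNifti::readNifti(image_path))
  lab <- as.array(RNifti::readNifti(label_path))
  stopifnot(all(dim(img) == dim(lab)))
  spacing <- RNifti::pixdim(RNifti::readNifti(image_path))[1:3]
  slices <- lapply(seq_len(dim(img)[3]), function(i) {
    masks <- list(lung = (lab[, , i] == 1) * 1L,
                  heart = (lab[, , i] == 2) * 1L,
                  cord = (lab[, , i] == 3) * 1L)
    new_labeled_slice(img[, , i], masks, NA_real_, basename(image_path), i)
  })
  structure(list(slices = slices, spacing = as.numeric(spacing)),
            class = "labeled_volume")
}

# organ names, in fixed order, used throughout the package
ORGANS <- c("lung", "heart", "cord")
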
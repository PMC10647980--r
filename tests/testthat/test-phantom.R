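test_that("identical config and seed regenerate bit-identical data", {
  cfg <- phantom_config(seed = 11)
  a <- generate_dataset(cfg, 5, rotated = TRUE)
  b <- generate_dataset(cfg, 5, rotated = TRUE)
  expect_identical(a, b)
  va <- generate_volume(cfg, 6, angle_deg = 4)
  vb <- generate_volume(cfg, 6, angle_deg = 4)
  expect_identical(va, vb)
})

test_that("slices satisfy their structural invariants", {
  cfg <- phantom_config(seed = 5)
  slices <- generate_dataset(cfg, 25, rotated = TRUE)
  for (s in slices) {
    expect_equal(dim(s$image), c(64, 64))
    for (m in s$masks) {
      expect_equal(dim(m), c(64, 64))
      expect_gt(sum(m), 0)
    }
    # pairwise disjoint
    expect_equal(sum(s$masks$lung * s$masks$heart), 0)
    expect_equal(sum(s$masks$lung * s$masks$cord), 0)
    expect_equal(sum(s$masks$heart * s$masks$cord), 0)
    # lung mask has exactly two connected components (8-connectivity)
    lab <- scosnet:::.label_cc(as.integer(s$masks$lung), 64L, 64L, 1L, 26L)
    expect_equal(attr(lab, "n_components"), 2L)
  }
})

test_that("organ areas mirror thoracic anatomy: lung > heart > cord", {
  cfg <- phantom_config(seed = 77)
  set.seed(77)
  for (k in 1:200) {
    s <- generate_slice(cfg)
    a <- vapply(s$masks, sum, 0)
    expect_true(a[["lung"]] > a[["heart"]])
    expect_true(a[["heart"]] > a[["cord"]])
  }
})

test_that("rotation flags control the angle distribution", {
  cfg <- phantom_config(seed = 9)
  expect_true(all(vapply(generate_dataset(cfg, 10, rotated = FALSE),
                         `[[`, 0, "angle_deg") == 0))
  ang <- vapply(generate_dataset(cfg, 800, rotated = TRUE),
                `[[`, 0, "angle_deg")
  expect_true(all(ang >= -30 & ang <= 30))
  expect_lt(abs(mean(ang)), 3)
  expect_lt(min(ang), -20)
  expect_gt(max(ang), 20)
  # degenerate interval pins the angle at zero
  cfg0 <- phantom_config(rotation_range_deg = c(0, 0), seed = 1)
  expect_equal(generate_dataset(cfg0, 3, rotated = TRUE)[[1]]$angle_deg, 0)
  expect_equal(length(generate_dataset(cfg0, 1)), 1L)
})

test_that("heart centroid sits between the lung centroids (spatial correlation)", {
  cfg <- phantom_config(seed = 123)
  set.seed(123)
  hits <- 0; n <- 500
  for (k in seq_len(n)) {
    s <- generate_slice(cfg, angle_deg = 0)
    lab <- scosnet:::.label_cc(as.integer(s$masks$lung), 64L, 64L, 1L, 26L)
    cl <- lapply(1:2, function(l) {
      ix <- which(matrix(lab == l, 64, 64), arr.ind = TRUE)
      colMeans(ix)
    })
    hc <- colMeans(which(s$masks$heart == 1, arr.ind = TRUE))
    rows <- range(cl[[1]][1], cl[[2]][1])
    cols <- range(cl[[1]][2], cl[[2]][2])
    if (hc[1] >= rows[1] && hc[1] <= rows[2] &&
        hc[2] >= cols[1] && hc[2] <= cols[2]) hits <- hits + 1
  }
  expect_gte(hits / n, 0.95)
})

test_that("volumes are coherent cases with smooth organ extent", {
  cfg <- phantom_config(seed = 3)
  v <- generate_volume(cfg, 20, angle_deg = 5)
  expect_s3_class(v, "labeled_volume")
  expect_equal(length(v$slices), 20L)
  expect_true(all(vapply(v$slices, `[[`, 0, "angle_deg") == 5))
  expect_true(all(vapply(v$slices, function(s) sum(s$masks$cord), 0) > 0))
  heart_px <- vapply(v$slices, function(s) sum(s$masks$heart), 0)
  expect_equal(heart_px[1], 0)
  expect_equal(heart_px[20], 0)
  # lungs/heart occupy one contiguous central run
  present <- which(heart_px > 0)
  expect_equal(present, seq(min(present), max(present)))
  expect_true(all(vapply(v$slices, function(s) s$slice_index, 0L) ==
                    seq_len(20)))
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(lung_size_range = c(0.4, 0.5)), "invalid config")
  expect_error(phantom_config(rotation_range_deg = c(-120, 0)),
               "invalid config")
  expect_error(phantom_config(cord_radius_range = c(-1, 2)), "invalid config")
  expect_error(phantom_config(lung_size_range = c(0.2, 0.1)), "invalid config")
})

test_that("NIfTI round-trip preserves images, labels and spacing", {
  cfg <- phantom_config(seed = 8)
  v <- generate_volume(cfg, 6, angle_deg = 3, spacing = c(1, 1, 5))
  ip <- tempfile(fileext = ".nii.gz"); lp <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(v, ip, lp)
  v2 <- read_volume_nifti(ip, lp)
  expect_equal(length(v2$slices), 6L)
  expect_equal(v2$spacing, c(1, 1, 5))
  for (i in seq_len(6)) {
    expect_equal(v2$slices[[i]]$masks$lung, v$slices[[i]]$masks$lung,
                 ignore_attr = TRUE)
    expect_equal(v2$slices[[i]]$masks$cord, v$slices[[i]]$masks$cord,
                 ignore_attr = TRUE)
    # NIfTI stores float32; allow its rounding on ~1000 HU magnitudes
    expect_lt(max(abs(v2$slices[[i]]$image - v$slices[[i]]$image)), 0.1)
  }
  unlink(c(ip, lp))
})
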
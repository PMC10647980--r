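test_that("binarisation is boundary-inclusive and idempotent", {
  expect_equal(sum(binarize(matrix(0.4, 3, 3), 0.5)), 0)
  expect_equal(as.numeric(binarize(matrix(c(0.49, 0.5, 0.51), 1), 0.5)),
               c(0, 1, 1))
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(binarize(binarize(m, 0.5), 0.5), binarize(m, 0.5))
  expect_error(binarize(m, 0))
})

test_that("directed distances are nearest-neighbour Euclidean distances", {
  A <- rbind(c(1, 1)); B <- rbind(c(4, 5))
  expect_equal(directed_distances(A, B), 5)  # 3-4-5 triangle
  A2 <- rbind(c(1, 1), c(2, 2), c(3, 3))
  expect_equal(length(directed_distances(A2, B)), nrow(A2))
  expect_equal(directed_distances(A, A), 0)
  # anisotropic spacing scales each axis
  expect_equal(directed_distances(rbind(c(1, 1)), rbind(c(2, 1)),
                                  spacing = c(5, 1)), 5)
  expect_error(directed_distances(A, A[0, , drop = FALSE]), "non-empty")
})

test_that("surface metrics satisfy their closed-form cases and conventions", {
  z <- matrix(0L, 24, 24)
  X <- z; X[5:9, 5:9] <- 1L
  expect_equal(max_hd(X, X), 0)
  expect_equal(hd95(X, X), 0)
  expect_equal(asd(X, X), 0)
  # single pixels two apart: ASD = (2 + 2) / (1 + 1) = 2
  a <- z; a[3, 3] <- 1L
  b <- z; b[3, 5] <- 1L
  expect_equal(asd(a, b), 2)
  expect_equal(max_hd(a, b), 2)
  # hand-derived percentile with linear interpolation: pooled distances
  # {0, 0, 20} give 0 + 0.9 * 20 = 18
  c1 <- z; c1[2, 2] <- 1L
  c2 <- z; c2[2, 2] <- 1L; c2[2, 22] <- 1L
  expect_equal(hd95(c1, c2), 18)
  # empty prediction: infinity convention; empty truth: an error
  expect_identical(max_hd(z, X), Inf)
  expect_identical(hd95(z, X), Inf)
  expect_identical(asd(z, X), Inf)
  expect_error(asd(X, z), "empty")
})

test_that("metrics match the brute-force oracle on random mask pairs", {
  set.seed(42)
  for (k in 1:30) {
    X <- random_mask(12, 12, 0.25)
    Y <- random_mask(12, 12, 0.25)
    expect_equal(max_hd(X, Y), oracle_max_hd(X, Y), tolerance = 1e-12)
    expect_equal(hd95(X, Y), oracle_hd95(X, Y), tolerance = 1e-12)
    expect_equal(asd(X, Y), oracle_asd(X, Y), tolerance = 1e-12)
  }
})

test_that("metrics are symmetric and translation invariant", {
  set.seed(5)
  place <- function(core, dr, dc) {
    m <- matrix(0L, 26, 26)
    m[(1 + dr):(8 + dr), (1 + dc):(8 + dc)] <- core
    m
  }
  for (k in 1:10) {
    cx <- random_mask(8, 8, 0.4)
    cy <- random_mask(8, 8, 0.4)
    X <- place(cx, 3, 3); Y <- place(cy, 3, 3)
    expect_equal(max_hd(X, Y), max_hd(Y, X))
    expect_equal(asd(X, Y), asd(Y, X))
    # joint shift of both masks leaves every metric unchanged
    X2 <- place(cx, 12, 9); Y2 <- place(cy, 12, 9)
    expect_equal(max_hd(X2, Y2), max_hd(X, Y))
    expect_equal(hd95(X2, Y2), hd95(X, Y))
    expect_equal(asd(X2, Y2), asd(X, Y))
  }
})

test_that("dilating the prediction away from the truth degrades ASD", {
  z <- matrix(0L, 30, 30)
  Y <- z; Y[13:18, 13:18] <- 1L
  grow <- function(m, k) {
    out <- z; out[(13 - k):(18 + k), (13 - k):(18 + k)] <- 1L; out
  }
  vals <- vapply(0:4, function(k) asd(grow(Y, k), Y), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("infinity counting and summaries follow the quartile conventions", {
  df <- data.frame(asd = c(0.5, Inf, 1.2, Inf))
  expect_equal(n_inf(df), 2L)
  expect_equal(n_inf(df[0, , drop = FALSE]), 0L)
  expect_equal(n_inf(df[c(3, 1, 2, 4), , drop = FALSE]), 2L)
  s <- summarize_metric(c(1, 2, 3, 4))
  expect_equal(s$q1, 1.75)
  expect_equal(s$median, 2.5)
  expect_equal(s$q3, 3.25)
  expect_equal(s$iqr, s$q3 - s$q1)
  expect_equal(s$n_inf, 0L)
  s2 <- summarize_metric(c(Inf, Inf))
  expect_equal(s2$n_inf, 2L)
  expect_true(is.na(s2$median))
  s3 <- summarize_metric(c(1, 5, Inf))
  expect_equal(s3$median, 3)  # quartiles over finite values only
  expect_equal(s3$n, 3L)
  expect_equal(s3$n_inf, 1L)
})

test_that("largest connected component keeps one deterministic winner", {
  v <- array(0L, c(8, 8, 4))
  v[2:4, 2:4, 2] <- 1L            # 9-voxel component
  v[7, 7, 4] <- 1L                # satellite
  out <- largest_cc_3d(v)
  expect_equal(sum(out), 9)
  expect_equal(out[7, 7, 4], 0L)
  single <- array(0L, c(5, 5, 2)); single[2:3, 2:3, 1] <- 1L
  expect_equal(largest_cc_3d(single), single)
  expect_equal(sum(largest_cc_3d(array(0L, c(4, 4, 2)))), 0)
  # 26-connectivity: diagonal voxels in adjacent slices connect
  diag3 <- array(0L, c(4, 4, 2)); diag3[1, 1, 1] <- 1L; diag3[2, 2, 2] <- 1L
  expect_equal(sum(largest_cc_3d(diag3)), 2)
  # tie between equal components: the one encountered first in linear
  # voxel order survives
  tie <- array(0L, c(6, 6, 1))
  tie[2, 2, 1] <- 1L  # linear index smaller
  tie[5, 5, 1] <- 1L
  out <- largest_cc_3d(tie)
  expect_equal(sum(out), 1)
  expect_equal(out[2, 2, 1], 1L)
})

test_that("case evaluation produces one record per present organ", {
  cfg <- phantom_config(seed = 6)
  set.seed(6)
  slices <- generate_dataset(cfg, 3)
  truth <- lapply(slices, function(s) s$masks)
  rec <- evaluate_masks(truth, truth, "2d")
  expect_equal(nrow(rec), 9)
  expect_true(all(rec$dice == 1))
  expect_true(all(rec$max_hd == 0 & rec$hd95 == 0 & rec$asd == 0))
  expect_equal(n_inf(rec), 0L)
  # an empty prediction marks that organ infinite without touching others
  pred <- truth
  pred[[2]]$heart <- pred[[2]]$heart * 0L
  rec <- evaluate_masks(pred, truth, "2d")
  bad <- rec[rec$case_id == "slice0002" & rec$organ == "heart", ]
  expect_true(bad$is_inf && is.infinite(bad$asd) && bad$dice == 0)
  expect_equal(n_inf(rec), 1L)
  # organs with empty ground truth are excluded, not scored
  truth2 <- truth
  truth2[[1]]$cord <- truth2[[1]]$cord * 0L
  rec2 <- evaluate_masks(truth2, truth2, "2d")
  expect_equal(nrow(rec2), 8)
  # probability inputs are thresholded
  predp <- lapply(truth, function(m) lapply(m, function(x) x * 0.9 + 0.01))
  rec3 <- evaluate_masks(predp, truth, "2d", threshold = 0.5)
  expect_true(all(rec3$dice == 1))
})

test_that("metric reports round-trip through CSV and JSON", {
  rec <- data.frame(case_id = c("a", "a"), organ = c("lung", "cord"),
                    dice = c(0.9, 0.5), max_hd = c(2, Inf),
                    hd95 = c(1, Inf), asd = c(0.3, Inf),
                    is_inf = c(FALSE, TRUE), stringsAsFactors = FALSE)
  csv <- tempfile(fileext = ".csv")
  write_metrics_csv(rec, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), 2)
  expect_true(is.infinite(back$asd[2]))
  js <- tempfile(fileext = ".json")
  write_summary_json(rec, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$cord_asd$n_inf, 1)
  expect_equal(parsed$lung_dice$median, 0.9)
  unlink(c(csv, js))
})

test_that("3D evaluation respects spacing and volume geometry", {
  z <- array(0L, c(10, 10, 4))
  Y <- z; Y[4:6, 4:6, 2:3] <- 1L
  X <- z; X[4:6, 4:6, 2] <- 1L   # missing one slice of the slab
  rec <- evaluate_masks(list(list(organ = X)), list(list(organ = Y)), "3d",
                        spacing = c(1, 1, 5), postprocess = FALSE)
  # the missing slab face is 5 mm away in the through-plane direction
  expect_equal(rec$max_hd, 5)
  recpx <- evaluate_masks(list(list(organ = X)), list(list(organ = Y)), "3d",
                          postprocess = FALSE)
  expect_equal(recpx$max_hd, 1)
  expect_error(evaluate_masks(list(list(organ = X)), list(list(organ = Y)),
                              "2d"), "dimensionality")
})
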
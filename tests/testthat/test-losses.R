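test_that("soft Dice matches its closed form", {
  y <- matrix(0, 6, 6); y[2:4, 2:4] <- 1
  expect_equal(soft_dice(y, y, smooth = 0), 1)
  expect_equal(soft_dice(y * 0, y, smooth = 1e-12), 0, tolerance = 1e-10)
  # pred = 0.5 on the truth support: 2(0.5|Y|) / (0.5|Y| + |Y|) = 2/3
  expect_equal(soft_dice(y * 0.5, y, smooth = 0), 2 / 3)
})

test_that("single-task loss is the negated batch-mean Dice", {
  y <- matrix(0, 4, 4); y[1:2, 1:2] <- 1
  r <- loss_stl(list(y, y), list(y, y), smooth = 0)
  expect_equal(r$total, -1)
  # second sample overlaps half of a two-pixel truth: Dice = 0.5
  y2 <- matrix(0, 4, 4); y2[1, 1:2] <- 1
  x2 <- matrix(0, 4, 4); x2[1, 1] <- 1; x2[3, 3] <- 1
  r <- loss_stl(list(y, x2), list(y, y2), smooth = 0)
  expect_equal(r$total, -0.75)
  expect_equal(loss_stl(y, y, smooth = 0)$total, -1)  # N = 1 reduces to -Dice
  expect_error(loss_stl(list(), list()), "empty")
})

test_that("joint loss sums one Dice term per organ", {
  y <- matrix(0, 4, 4); y[1:2, 1:2] <- 1
  preds <- list(lung = y, heart = y, cord = y)
  r <- loss_scos(preds, preds, smooth = 0)
  expect_equal(r$total, -3)
  expect_equal(unname(r$per_term), c(1, 1, 1))
  # all-zero predictions against non-empty truths vanish in the smooth -> 0 limit
  zero <- lapply(preds, function(m) m * 0)
  expect_equal(loss_scos(zero, preds, smooth = 1e-12)$total, 0,
               tolerance = 1e-9)
  # bookkeeping identity: total is the negated sum of the per-organ terms
  set.seed(1)
  pr <- lapply(preds, function(m) matrix(runif(16), 4, 4))
  r <- loss_scos(pr, preds)
  expect_equal(r$total, -sum(r$per_term), tolerance = 1e-6)
  expect_error(loss_scos(pr[1:2], preds), "heads")
})

test_that("distance loss is the per-image sum of squared errors", {
  g <- matrix(c(1, 0, 0, 0), 2, 2)
  p <- matrix(0, 2, 2)
  expect_equal(loss_distance(p, g), 1)
  expect_equal(loss_distance(g, g), 0)
  set.seed(2)
  a <- matrix(runif(16), 4); b <- matrix(runif(16), 4)
  expect_equal(loss_distance(3 * a, 3 * b), 9 * loss_distance(a, b))
})

test_that("multi-task losses are unweighted sums of their terms", {
  y <- matrix(0, 4, 4); y[1:2, 1:2] <- 1
  seg <- list(lung = y, heart = y, cord = y)
  dmap <- distance_map(seg)
  r1 <- loss_tasks1(seg, seg, dmap, dmap, smooth = 0)
  expect_equal(r1$total, -3)
  expect_named(r1$per_term, c("dice_lung", "dice_heart", "dice_cord",
                              "distance"))
  cont <- lapply(seg, contour_map)
  r2 <- loss_tasks2(seg, seg, cont, cont, dmap, dmap, smooth = 0)
  expect_equal(r2$total, -6)
  expect_true(all(c("contour_lung", "contour_heart", "contour_cord") %in%
                    names(r2$per_term)))
  # zeroing the distance head changes only the distance term
  r1b <- loss_tasks1(seg, seg, dmap * 0, dmap, smooth = 0)
  expect_equal(r1b$per_term[["distance"]] - r1$per_term[["distance"]],
               sum(dmap^2))
  expect_equal(r1b$per_term[names(r1$per_term) != "distance"],
               r1$per_term[names(r1$per_term) != "distance"])
  # report invariant: total equals the stated combination of per-term values
  expect_equal(r2$total,
               -sum(r2$per_term[startsWith(names(r2$per_term), "dice")]) -
                 sum(r2$per_term[startsWith(names(r2$per_term), "contour")]) +
                 r2$per_term[["distance"]],
               tolerance = 1e-6)
})

test_that("dice-based losses are bounded by the number of summed terms", {
  set.seed(3)
  y <- matrix(0, 4, 4); y[2:3, 2:3] <- 1
  for (k in 1:20) {
    pr <- list(lung = matrix(runif(16), 4), heart = matrix(runif(16), 4),
               cord = matrix(runif(16), 4))
    tot <- loss_scos(pr, list(lung = y, heart = y, cord = y))$total
    expect_gte(tot, -3); expect_lte(tot, 0)
  }
})

test_that("training engine loss agrees with the reference R losses", {
  bb <- tiny_backbone(2, 3)
  m <- build_model(bb, "SCOS", seed = 4)
  set.seed(4)
  H <- 8; W <- 8; N <- 3
  img <- array(runif(H * W * N), c(H, W, N))
  tg <- list(lung = array(as.numeric(runif(H * W * N) > 0.6), c(H, W, N)),
             heart = array(as.numeric(runif(H * W * N) > 0.7), c(H, W, N)),
             cord = array(as.numeric(runif(H * W * N) > 0.9), c(H, W, N)))
  eng <- scosnet:::.unet_loss(scosnet:::net_ptr(m), img, tg, 1e-6)
  pr <- scosnet:::.unet_predict(scosnet:::net_ptr(m), img)
  ref <- loss_scos(lapply(pr, scosnet:::as_batch),
                   lapply(tg, scosnet:::as_batch), smooth = 1e-6)
  expect_equal(eng$total, ref$total, tolerance = 1e-5)
  for (org in ORG)
    expect_equal(eng$per_term[[paste0("dice_", org)]],
                 unname(ref$per_term[[paste0("dice_", org)]]),
                 tolerance = 1e-5)
})

test_that("analytic loss gradients match finite differences", {
  bb <- tiny_backbone(2, 2)
  ts <- task_setting("TASKS1")
  ptr <- scosnet:::make_net_ptr(bb, ts, 7)
  set.seed(7)
  H <- 8; W <- 8; N <- 2
  img <- array(runif(H * W * N), c(H, W, N))
  tg <- list(lung = array(as.numeric(runif(H * W * N) > 0.6), c(H, W, N)),
             heart = array(as.numeric(runif(H * W * N) > 0.7), c(H, W, N)),
             cord = array(as.numeric(runif(H * W * N) > 0.9), c(H, W, N)),
             distance = array(runif(H * W * N), c(H, W, N)))
  g <- scosnet:::.unet_grads(ptr, img, tg, 1e-6)
  w0 <- scosnet:::.unet_get_weights(ptr)
  eps <- 3e-3
  fd <- function(layer, i) {
    wp <- w0; wp[[layer]]$W[i] <- wp[[layer]]$W[i] + eps
    scosnet:::.unet_set_weights(ptr, wp)
    lp <- scosnet:::.unet_loss(ptr, img, tg, 1e-6)$total
    wm <- w0; wm[[layer]]$W[i] <- wm[[layer]]$W[i] - eps
    scosnet:::.unet_set_weights(ptr, wm)
    lm <- scosnet:::.unet_loss(ptr, img, tg, 1e-6)$total
    (lp - lm) / (2 * eps)
  }
  set.seed(8)
  for (layer in names(w0)) {
    for (i in sample(length(w0[[layer]]$W), min(3, length(w0[[layer]]$W)))) {
      num <- fd(layer, i)
      ana <- g[[layer]]$W[i]
      # single-precision forward passes limit finite-difference accuracy
      expect_lt(abs(ana - num), 0.05 * max(1, abs(num)))
    }
  }
})
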
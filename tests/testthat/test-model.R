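test_that("task settings declare the paper's head compositions", {
  expect_equal(task_setting("STL_lung")$heads$head, "lung")
  expect_equal(task_setting("SCOS")$heads$head, c("lung", "heart", "cord"))
  t1 <- task_setting("TASKS1")
  expect_equal(nrow(t1$heads), 4)
  expect_equal(t1$heads$activation[t1$heads$head == "distance"], "linear")
  t2 <- task_setting("TASKS2")
  expect_equal(nrow(t2$heads), 7)
  expect_equal(sum(t2$heads$loss == "dice"), 6)
  expect_error(task_setting("SCOSX"))
})

test_that("every head output matches the input size across configurations", {
  for (cfgrow in list(list(2L, 2L, c(8, 8)), list(2L, 4L, c(12, 16)),
                      list(3L, 2L, c(16, 16)), list(3L, 4L, c(8, 24)))) {
    m <- build_model(backbone_config(cfgrow[[1]], cfgrow[[2]]), "SCOS",
                     seed = 1)
    hw <- cfgrow[[3]]
    img <- array(rnorm(prod(hw) * 2, 40, 80), c(hw, 2))
    pr <- predict(m, img)
    expect_equal(length(pr), 3)
    for (p in pr) expect_equal(dim(p), c(hw, 2))
  }
  # indivisible input sizes are refused
  m <- build_model(backbone_config(3, 2), "SCOS", seed = 1)
  expect_error(predict(m, matrix(0, 10, 12)), "divisible")
})

test_that("sigmoid heads emit probabilities and inference is deterministic", {
  m <- build_model(tiny_backbone(2, 3), "TASKS1", seed = 2)
  img <- array(rnorm(8 * 8, 40, 100), c(8, 8, 1))
  p1 <- predict(m, img); p2 <- predict(m, img)
  expect_identical(p1, p2)
  for (org in ORG) expect_true(all(p1[[org]] > 0 & p1[[org]] < 1))
  pm <- predict(m, img, type = "mask")
  expect_true(all(pm$lung %in% c(0L, 1L)))
  expect_false(all(pm$distance %in% c(0L, 1L)))  # regression head untouched
})

test_that("parameter counts follow the closed form; joint vs single differ by two heads", {
  for (depth in 2:3) for (bf in c(2L, 4L, 8L)) {
    bb <- backbone_config(depth, bf)
    for (st in c("STL_lung", "SCOS", "TASKS1", "TASKS2")) {
      m <- build_model(bb, st, seed = 1)
      expect_equal(n_params(m), param_count(bb, st))
    }
    # the only difference between the joint and single-task models is two
    # extra 1x1 head layers (backbone shared)
    expect_equal(param_count(bb, "SCOS") - param_count(bb, "STL_lung"),
                 2 * (bf + 1))
  }
})

test_that("one backbone is shared by all heads of a model", {
  m <- build_model(tiny_backbone(3, 2), "TASKS2", seed = 3)
  info <- layer_info(m)
  # each backbone layer appears exactly once; heads are the only extras
  expect_equal(sum(info$layer == "dec1_conv2"), 1)
  expect_equal(sum(startsWith(info$layer, "head_")), 7)
  expect_equal(sum(duplicated(info$layer)), 0)
})

test_that("identical seeds build identical weights and training runs", {
  bb <- tiny_backbone(2, 2)
  m1 <- build_model(bb, "SCOS", seed = 9)
  m2 <- build_model(bb, "SCOS", seed = 9)
  expect_identical(coef(m1), coef(m2))
  m3 <- build_model(bb, "SCOS", seed = 10)
  expect_false(identical(coef(m1), coef(m3)))
  cfg <- phantom_config(seed = 12)
  train <- generate_dataset(cfg, 8)
  f1 <- scosnet(train, "SCOS", bb, epochs = 2, seed = 5)
  f2 <- scosnet(train, "SCOS", bb, epochs = 2, seed = 5)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$history, f2$history)
})

test_that("weights survive a set/get round-trip and rebuild the same model", {
  m <- build_model(tiny_backbone(2, 3), "SCOS", seed = 4)
  img <- array(rnorm(8 * 8, 0, 100), c(8, 8, 1))
  p1 <- predict(m, img)
  # drop the live handle; predict must rebuild from the stored weights
  m$.env$ptr <- NULL
  p2 <- predict(m, img)
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("a short optimisation run reduces every setting's loss", {
  cfg <- phantom_config(seed = 31)
  train <- generate_dataset(cfg, 16)
  for (st in c("STL_cord", "SCOS", "TASKS1", "TASKS2")) {
    f <- scosnet(train, st, tiny_backbone(2, 4), epochs = 8, seed = 2)
    expect_s3_class(f, "scosnet")
    expect_equal(nrow(f$history), 8)
    expect_lt(tail(f$history$train, 1), f$history$train[1])
  }
})

test_that("augmented training runs and never sees a fixed orientation", {
  cfg <- phantom_config(seed = 13)
  train <- generate_dataset(cfg, 8)
  f <- scosnet(train, "SCOS", tiny_backbone(2, 2), epochs = 2, seed = 3,
               augment = TRUE, augment_range = c(-30, 30))
  expect_true(f$augment)
  expect_true(is.finite(tail(f$history$train, 1)))
})

test_that("print, summary, plot and coef methods work", {
  m <- build_model(tiny_backbone(2, 2), "SCOS", seed = 1)
  expect_output(print(m), "Untrained")
  expect_type(coef(m), "list")
  cfg <- phantom_config(seed = 1)
  f <- scosnet(generate_dataset(cfg, 8), "SCOS", tiny_backbone(2, 2),
               epochs = 2, seed = 1)
  expect_output(print(f), "Fitted")
  expect_output(summary(f), "Layers")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})

test_that("away from borders, a constant input yields a constant output", {
  m <- build_model(tiny_backbone(2, 2), "SCOS", seed = 6)
  img <- matrix(0, 32, 32)
  p <- predict(m, array(img, c(32, 32, 1)))$lung[, , 1]
  # translation equivariance of padded convolutions: pixels whose receptive
  # field (side 18 at depth 2) stays clear of the border share one value
  interior <- p[12:21, 12:21]
  # single-precision gemm may order its sums differently per output row
  expect_lt(diff(range(interior)), 1e-4)
})
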
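#' Backbone configuration
#'
#' The shared encoder-decoder: per resolution level two 3x3 same-padded
#' convolutions with rectified-linear activations followed by 2x2
#' max-pooling; the decoder mirrors it with 2x2 stride-2 transposed
#' convolutions and skip concatenations; every task head is a 1x1
#' convolution on the last decoder feature. Filter counts double per level
#' down and halve per level up. Spatial output size always equals input
#' size; inputs must be divisible by `2^(depth - 1)`.
#'
#' The desk-scale default (`depth = 3`, `base_filters = 8`, 64x64 inputs) is
#' CPU-trainable; the full-scale reference (`depth = 5`, `base_filters = 32`,
#' 256x512 inputs, half the filter budget of the original U-net) is
#' constructible with the same code.
#'
#' @param depth number of resolution levels (>= 2).
#' @param base_filters filter count at the first level (>= 1).
#' @param in_channels input channels (CT slices: 1).
#' @return object of class `"backbone_config"`.
#' @export
backbone_config <- function(depth = 3L, base_filters = 8L, in_channels = 1L) {
  stopifnot(depth >= 2, base_filters >= 1, in_channels >= 1)
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 in_channels = as.integer(in_channels),
                 conv_kernel = c(3L, 3L), up_kernel = c(2L, 2L),
                 up_stride = c(2L, 2L)),
            class = "backbone_config")
}

SETTINGS <- c("STL_lung", "STL_heart", "STL_cord", "SCOS", "TASKS1", "TASKS2")

#' Learning-task setting
#'
#' Declarative description of a model's output heads and loss composition:
#' \describe{
#'   \item{STL_lung / STL_heart / STL_cord}{one sigmoid segmentation head
#'     trained with Dice loss (single-task learning).}
#'   \item{SCOS}{three sigmoid segmentation heads (lung, heart, cord), one
#'     Dice loss per organ, summed.}
#'   \item{TASKS1}{the three segmentation heads plus a linear distance-map
#'     regression head (sum-of-squares loss).}
#'   \item{TASKS2}{TASKS1 plus three sigmoid contour heads with Dice loss.}
#' }
#' All heads share one backbone; the settings differ only in their 1x1 head
#' layers and loss terms, so comparisons isolate the effect of the task
#' composition.
#'
#' @param name one of `"STL_lung"`, `"STL_heart"`, `"STL_cord"`, `"SCOS"`,
#'   `"TASKS1"`, `"TASKS2"`.
#' @return object of class `"task_setting"` with a `heads` data frame
#'   (`head`, `activation`, `loss`).
#' @export
task_setting <- function(name = SETTINGS) {
  name <- match.arg(name)
  seg <- data.frame(head = ORGANS, activation = "sigmoid", loss = "dice",
                    stringsAsFactors = FALSE)
  heads <- switch(
    name,
    STL_lung = seg[seg$head == "lung", ],
    STL_heart = seg[seg$head == "heart", ],
    STL_cord = seg[seg$head == "cord", ],
    SCOS = seg,
    TASKS1 = rbind(seg, data.frame(head = "distance", activation = "linear",
                                   loss = "sse")),
    TASKS2 = rbind(seg,
                   data.frame(head = paste0("contour_", ORGANS),
                              activation = "sigmoid", loss = "dice"),
                   data.frame(head = "distance", activation = "linear",
                              loss = "sse")))
  rownames(heads) <- NULL
  structure(list(name = name, heads = heads), class = "task_setting")
}

#' @export
print.task_setting <- function(x, ...) {
  cat(sprintf("<task_setting %s: %d head(s): %s>\n", x$name, nrow(x$heads),
              paste(x$heads$head, collapse = ", ")))
  invisible(x)
}

act_code <- function(a) c(linear = 0L, relu = 1L, sigmoid = 2L)[[a]]
loss_code <- function(l) c(dice = 0L, sse = 1L)[[l]]

make_net_ptr <- function(backbone, setting, seed) {
  .unet_create(backbone$depth, backbone$base_filters, backbone$in_channels,
               setting$heads$head,
               vapply(setting$heads$activation, act_code, 0L),
               vapply(setting$heads$loss, loss_code, 0L),
               as.integer(seed))
}

#' Closed-form parameter count of a configuration
#'
#' Counted from the layer arithmetic alone, independently of the compiled
#' network: `(9 * in + 1) * out` per 3x3 convolution, `(4 * in + 1) * out`
#' per transposed convolution, `(in + 1)` per 1x1 head.
#'
#' @param backbone a [backbone_config()].
#' @param setting a [task_setting()] or setting name.
#' @return total number of trainable parameters.
#' @export
param_count <- function(backbone, setting) {
  if (is.character(setting)) setting <- task_setting(setting)
  D <- backbone$depth; F0 <- backbone$base_filters
  conv3 <- function(ic, oc) (9 * ic + 1) * oc
  up2 <- function(ic, oc) (4 * ic + 1) * oc
  total <- 0
  ic <- backbone$in_channels
  for (l in 0:(D - 2)) {
    f <- F0 * 2^l
    total <- total + conv3(ic, f) + conv3(f, f)
    ic <- f
  }
  fb <- F0 * 2^(D - 1)
  total <- total + conv3(ic, fb) + conv3(fb, fb)
  ic <- fb
  for (l in (D - 2):0) {
    f <- F0 * 2^l
    total <- total + up2(ic, f) + conv3(2 * f, f) + conv3(f, f)
    ic <- f
  }
  total + nrow(setting$heads) * (ic + 1)
}

# targets for each head of a setting, from one slice's masks
head_targets <- function(heads, masks) {
  out <- list()
  for (h in heads$head) {
    out[[h]] <- if (h %in% ORGANS) masks[[h]] * 1
    else if (startsWith(h, "contour_")) contour_map(masks[[sub("contour_", "", h)]])
    else if (h == "distance") distance_map(masks[ORGANS])
    else stop("unknown head '", h, "'")
  }
  out
}

# slices -> list(images = HxWxN array in [0,1], slices01 = windowed slices)
prepare_inputs <- function(slices, window) {
  stopifnot(length(slices) > 0)
  rng <- window$out_max - window$out_min
  sl01 <- lapply(slices, function(s) {
    img <- (window_intensity(s$image, window) - window$out_min) / rng
    new_labeled_slice(img, s$masks, s$angle_deg, s$case_id, s$slice_index)
  })
  H <- nrow(sl01[[1]]$image); W <- ncol(sl01[[1]]$image)
  imgs <- array(0, c(H, W, length(sl01)))
  for (i in seq_along(sl01)) imgs[, , i] <- sl01[[i]]$image
  list(images = imgs, slices01 = sl01)
}

stack_targets <- function(heads, slices) {
  H <- nrow(slices[[1]]$image); W <- ncol(slices[[1]]$image)
  out <- list()
  for (h in heads$head) out[[h]] <- array(0, c(H, W, length(slices)))
  for (i in seq_along(slices)) {
    tg <- head_targets(heads, slices[[i]]$masks)
    for (h in heads$head) out[[h]][, , i] <- tg[[h]]
  }
  out
}

new_scosnet <- function(backbone, setting, weights, seed, window,
                        history = NULL, trained = FALSE, augment = FALSE,
                        augment_range = c(-30, 30), epochs = 0L,
                        batch_size = 8L, learning_rate = 1e-3,
                        smooth = 1e-6, call = sys.call(-1)) {
  env <- new.env(parent = emptyenv())
  structure(list(backbone = backbone, setting = setting, weights = weights,
                 seed = seed, window = window, history = history,
                 trained = trained, augment = augment,
                 augment_range = augment_range, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 smooth = smooth, call = call, .env = env),
            class = "scosnet")
}

# lazily (re)build the compiled network for a fitted object
net_ptr <- function(object) {
  env <- object$.env
  ok <- !is.null(env$ptr) &&
    !inherits(try(.unet_layer_info(env$ptr), silent = TRUE), "try-error")
  if (!ok) {
    env$ptr <- make_net_ptr(object$backbone, object$setting, object$seed)
    .unet_set_weights(env$ptr, object$weights)
  }
  env$ptr
}

#' Build an untrained model
#'
#' Constructs the shared backbone with the setting's head layers and
#' He-uniform initial weights (seeded, reproducible). The returned object is
#' a `"scosnet"` exactly like a fitted one, usable with [predict.scosnet()]
#' and the interpretation tools, just with zero training epochs.
#'
#' @param backbone a [backbone_config()].
#' @param setting a [task_setting()] or setting name.
#' @param seed integer seed for weight initialisation.
#' @param window intensity [window_spec()] recorded for prediction-time
#'   preprocessing.
#' @return an object of class `"scosnet"`.
#' @export
build_model <- function(backbone = backbone_config(), setting = "SCOS",
                        seed = 1L, window = window_spec()) {
  if (is.character(setting)) setting <- task_setting(setting)
  ptr <- make_net_ptr(backbone, setting, seed)
  obj <- new_scosnet(backbone, setting, .unet_get_weights(ptr), seed, window)
  obj$.env$ptr <- ptr
  obj
}

#' Fit a multi-task organ segmentation network
#'
#' Trains the configured task setting on labelled slices with adaptive moment
#' estimation (Adam) on the setting's loss: Dice loss per segmentation or
#' contour head (negated, summed) plus a sum-of-squares term for the distance
#' head where present. Images are windowed to \[0, 1\] internally; targets
#' (masks, contour maps, distance maps) are derived from the slice masks.
#' With `augment = TRUE`, each sample is rotated by a fresh uniform angle
#' every time it is drawn (online augmentation; the training set is never
#' inflated), and targets are recomputed from the rotated masks.
#'
#' Training is deterministic given `seed`, which controls weight
#' initialisation, batch shuffling and augmentation angles.
#'
#' @param data list of `"labeled_slice"` training samples (unrotated, unless
#'   you deliberately feed rotated ones).
#' @param setting a [task_setting()] or setting name (default `"SCOS"`).
#' @param backbone a [backbone_config()].
#' @param epochs training epochs (fixed budget; no early stopping).
#' @param batch_size samples per Adam step.
#' @param learning_rate Adam step size.
#' @param augment online random rotation augmentation.
#' @param augment_range rotation interval in degrees when augmenting.
#' @param val_data optional validation slices; their loss is logged per epoch.
#' @param seed integer seed.
#' @param smooth Dice smoothing constant used during training (evaluation
#'   Dice is computed on hard masks without smoothing).
#' @param window intensity [window_spec()].
#' @param verbose print per-epoch losses.
#' @return an object of class `"scosnet"`: the trained weights plus
#'   configuration and a per-epoch `history` data frame (`epoch`, `train`,
#'   `val`, and one column per loss term, e.g. `dice_lung`), ready for
#'   `write.csv()`.
#' @seealso [predict.scosnet()], [build_model()], [run_study()]
#' @export
#' @examples
#' \donttest{
#' cfg <- phantom_config(seed = 7)
#' train <- generate_dataset(cfg, 16)
#' fit <- scosnet(train, "SCOS", backbone_config(depth = 2, base_filters = 4),
#'                epochs = 2, seed = 1)
#' pr <- predict(fit, train[1:2])
#' str(pr$lung)
#' }
scosnet <- function(data, setting = "SCOS", backbone = backbone_config(),
                    epochs = 60L, batch_size = 8L, learning_rate = 1e-3,
                    augment = FALSE, augment_range = c(-30, 30),
                    val_data = NULL, seed = 1L, smooth = 1e-6,
                    window = window_spec(), verbose = FALSE) {
  if (is.character(setting)) setting <- task_setting(setting)
  stopifnot(inherits(setting, "task_setting"),
            inherits(backbone, "backbone_config"), length(data) >= 1)
  heads <- setting$heads
  prep <- prepare_inputs(data, window)
  N <- length(data)
  targets <- if (!augment) stack_targets(heads, prep$slices01) else NULL
  vprep <- NULL; vtargets <- NULL
  if (!is.null(val_data)) {
    vprep <- prepare_inputs(val_data, window)
    vtargets <- stack_targets(heads, vprep$slices01)
  }
  ptr <- make_net_ptr(backbone, setting, seed)
  set.seed(seed)
  hist <- NULL
  H <- dim(prep$images)[1]; W <- dim(prep$images)[2]
  for (ep in seq_len(epochs)) {
    perm <- sample.int(N)
    if (augment) {
      # online augmentation: every sample gets a fresh angle this epoch
      bs <- lapply(prep$slices01[perm], random_rotation_augment,
                   range_deg = augment_range, fill = 0)
      ep_images <- array(0, c(H, W, N))
      for (i in seq_len(N)) ep_images[, , i] <- bs[[i]]$image
      r <- .unet_train_epoch(ptr, ep_images, stack_targets(heads, bs),
                             seq_len(N), batch_size, learning_rate, smooth)
    } else {
      r <- .unet_train_epoch(ptr, prep$images, targets, perm, batch_size,
                             learning_rate, smooth)
    }
    if (!is.finite(r$total))
      stop("training diverged: non-finite loss at epoch ", ep)
    vl <- if (!is.null(vtargets))
      .unet_loss(ptr, vprep$images, vtargets, smooth)$total else NA_real_
    row <- data.frame(epoch = ep, train = r$total, val = vl)
    for (nm in names(r$per_term)) row[[nm]] <- r$per_term[[nm]]
    hist <- rbind(hist, row)
    if (verbose)
      cat(sprintf("epoch %3d  train %.4f  val %s\n", ep, r$total,
                  ifelse(is.na(vl), "-", sprintf("%.4f", vl))))
  }
  obj <- new_scosnet(backbone, setting, .unet_get_weights(ptr), seed, window,
                     history = hist, trained = epochs > 0, augment = augment,
                     augment_range = augment_range, epochs = epochs,
                     batch_size = batch_size, learning_rate = learning_rate,
                     smooth = smooth, call = match.call())
  obj$.env$ptr <- ptr
  obj
}

# coerce prediction input to a windowed [0,1] image array
newdata_to_array <- function(object, newdata) {
  if (inherits(newdata, "labeled_slice")) newdata <- list(newdata)
  if (is.list(newdata) && length(newdata) > 0 &&
      inherits(newdata[[1]], "labeled_slice"))
    return(prepare_inputs(newdata, object$window)$images)
  if (is.matrix(newdata)) dim(newdata) <- c(dim(newdata), 1L)
  stopifnot(is.array(newdata), length(dim(newdata)) == 3)
  w <- object$window
  (window_intensity(newdata, w) - w$out_min) / (w$out_max - w$out_min)
}

#' Predict with a fitted (or freshly built) model
#'
#' Raw-intensity inputs are windowed with the model's recorded window spec;
#' outputs are one `H x W x N` array per head. Sigmoid heads produce
#' probabilities in (0, 1); the distance head is unbounded. Inference is
#' deterministic.
#'
#' @param object a `"scosnet"`.
#' @param newdata list of `"labeled_slice"`, a matrix (one HU image), or an
#'   `H x W x N` array of HU images.
#' @param type `"prob"` for raw head outputs, `"mask"` to binarise the
#'   sigmoid heads at `threshold` (the distance head is returned as-is).
#' @param threshold see [binarize()].
#' @param ... unused.
#' @return named list of per-head arrays.
#' @export
predict.scosnet <- function(object, newdata, type = c("prob", "mask"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  arr <- newdata_to_array(object, newdata)
  out <- .unet_predict(net_ptr(object), arr)
  if (type == "mask") {
    sig <- object$setting$heads$head[object$setting$heads$activation == "sigmoid"]
    for (h in sig) out[[h]] <- binarize(out[[h]], threshold)
  }
  out
}

#' @export
coef.scosnet <- function(object, ...) object$weights

#' Number of trainable parameters of a fitted model
#'
#' @param object a `"scosnet"`.
#' @return integer count (matches [param_count()] on the same configuration).
#' @export
n_params <- function(object) {
  info <- .unet_layer_info(net_ptr(object))
  sum(info$n_weights) + sum(info$n_bias)
}

#' Layer inventory of the compiled network
#'
#' @param object a `"scosnet"`.
#' @return data frame with layer names, channel counts and parameter sizes.
#' @export
layer_info <- function(object) .unet_layer_info(net_ptr(object))

#' @export
print.scosnet <- function(x, ...) {
  cat(sprintf("%s network (%s), depth %d, base filters %d, %d parameters\n",
              if (x$trained) "Fitted" else "Untrained", x$setting$name,
              x$backbone$depth, x$backbone$base_filters, n_params(x)))
  cat(sprintf("heads: %s\n", paste(x$setting$heads$head, collapse = ", ")))
  if (x$trained) {
    cat(sprintf("trained %d epochs (batch %d, lr %g%s); final train loss %.4f\n",
                x$epochs, x$batch_size, x$learning_rate,
                if (x$augment) sprintf(", rotation augmentation %g..%g deg",
                                       x$augment_range[1], x$augment_range[2])
                else "",
                tail(x$history$train, 1)))
  }
  invisible(x)
}

#' @export
summary.scosnet <- function(object, ...) {
  print(object)
  cat("\nLayers:\n")
  print(layer_info(object))
  if (object$trained) {
    cat("\nLoss history (last 5 epochs):\n")
    print(tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.scosnet <- function(x, ...) {
  if (!x$trained || is.null(x$history)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  h <- x$history
  ylim <- range(c(h$train, h$val), na.rm = TRUE)
  plot(h$epoch, h$train, type = "l", xlab = "epoch", ylab = "loss",
       ylim = ylim, main = sprintf("%s training", x$setting$name), ...)
  if (any(is.finite(h$val))) {
    lines(h$epoch, h$val, lty = 2)
    legend("topright", c("train", "validation"), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
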
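# Interpretation toolkit: guided grad-CAM, input-gradient maps, average
# feature maps, and analytic receptive fields.

new_attribution_map <- function(values, kind, head = NA_character_,
                                layer = NA_character_) {
  stopifnot(all(is.finite(values)))
  structure(list(values = values, kind = kind, head = head, layer = layer),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("<attribution_map %s head=%s layer=%s  %dx%d range [%.3g, %.3g]>\n",
              x$kind, x$head, x$layer, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.attribution_map <- function(x, ...) {
  image(t(x$values)[, nrow(x$values):1], axes = FALSE, useRaster = TRUE,
        main = sprintf("%s (%s)", x$kind, x$head), ...)
  invisible(x)
}

# bilinear resize of a matrix to H x W (pixel-centre aligned)
bilinear_resize <- function(m, H, W) {
  hi <- nrow(m); wi <- ncol(m)
  if (hi == H && wi == W) return(m)
  sy <- pmin(pmax((seq_len(H) - 0.5) * hi / H + 0.5, 1), hi)
  sx <- pmin(pmax((seq_len(W) - 0.5) * wi / W + 0.5, 1), wi)
  y0 <- pmin(floor(sy), hi - 1); x0 <- pmin(floor(sx), wi - 1)
  fy <- sy - y0; fx <- sx - x0
  a <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    m[y0 + 1, x0, drop = FALSE] * outer(fy, 1 - fx) +
    m[y0, x0 + 1, drop = FALSE] * outer(1 - fy, fx) +
    m[y0 + 1, x0 + 1, drop = FALSE] * outer(fy, fx)
  a
}

interpret_input <- function(object, input) {
  if (inherits(input, "labeled_slice")) input <- input$image
  stopifnot(is.matrix(input))
  w <- object$window
  (window_intensity(input, w) - w$out_min) / (w$out_max - w$out_min)
}

# scalarisation weight over the head's output: the predicted region
# (probability >= 0.5), falling back to all pixels when nothing is predicted
prediction_weight <- function(p) {
  w <- (p >= 0.5) * 1
  if (sum(w) == 0) w[] <- 1
  w
}

#' Guided grad-CAM attribution for one task head
#'
#' Combines guided back-propagation with a gradient class-activation map for
#' dense prediction. The scalar target is the sum of the head's output
#' probabilities over the predicted region (output >= 0.5; all pixels if the
#' prediction is empty). The CAM is the rectified, gradient-weighted channel
#' sum of the chosen layer's activations, bilinearly upsampled to input
#' size; the guided-backprop map is the input gradient computed with
#' backward rectification at every rectified-linear unit. The returned map
#' is their elementwise product, so it is zero wherever the CAM is zero.
#'
#' Works on untrained models too (the maps are defined regardless).
#'
#' @param object a `"scosnet"`.
#' @param input a `"labeled_slice"` or raw-intensity matrix.
#' @param head head name (e.g. `"lung"`).
#' @param cam_layer layer whose activations drive the CAM; the default is
#'   the last decoder convolution before the heads.
#' @return an `"attribution_map"` (kind `"guided_gradcam"`).
#' @export
guided_gradcam <- function(object, input, head, cam_layer = "dec1_conv2") {
  img <- interpret_input(object, input)
  ptr <- net_ptr(object)
  p <- .unet_predict(ptr, array(img, c(dim(img), 1L)))[[head]][, , 1]
  at <- .unet_attribution(ptr, img, head, prediction_weight(p),
                          guided = TRUE, cam_layer = cam_layer)
  grads <- at$cam_grad
  alpha <- apply(grads, 3, mean)
  cam <- matrix(0, dim(at$cam_act)[1], dim(at$cam_act)[2])
  for (k in seq_along(alpha)) cam <- cam + alpha[k] * at$cam_act[, , k]
  cam <- pmax(cam, 0)
  cam_up <- bilinear_resize(cam, nrow(img), ncol(img))
  new_attribution_map(cam_up * at$input_grad, "guided_gradcam", head,
                      cam_layer)
}

#' Input-gradient map for one task head
#'
#' The absolute gradient of the head's summed output probability with
#' respect to the input image, `G(x) = |dS/dI(x)|` with
#' `S = sum_pixels p(x)`, normalised to \[0, 1\] by its maximum (left as-is
#' when identically zero). Large values mark input pixels that the task
#' actually consults.
#'
#' @inheritParams guided_gradcam
#' @return an `"attribution_map"` (kind `"gradient"`).
#' @export
gradient_map <- function(object, input, head) {
  img <- interpret_input(object, input)
  ptr <- net_ptr(object)
  w <- matrix(1, nrow(img), ncol(img))
  at <- .unet_attribution(ptr, img, head, w, guided = FALSE, cam_layer = "")
  g <- abs(at$input_grad)
  if (max(g) > 0) g <- g / max(g)
  new_attribution_map(g, "gradient", head)
}

#' Average feature map of a layer
#'
#' The channel mean of a layer's activation, bilinearly interpolated to the
#' input size; optionally alpha-blended with the (windowed) input image for
#' display.
#'
#' @inheritParams guided_gradcam
#' @param layer layer name (see [layer_info()]); e.g. `"bottleneck_conv2"`
#'   for the last convolution of the encoding path.
#' @param blend_alpha if not `NULL`, return
#'   `blend_alpha * map + (1 - blend_alpha) * input` after scaling both to
#'   \[0, 1\].
#' @return an `"attribution_map"` (kind `"avg_feature"`).
#' @export
avg_feature_map <- function(object, input, layer = "bottleneck_conv2",
                            blend_alpha = NULL) {
  img <- interpret_input(object, input)
  acts <- .unet_forward_capture(net_ptr(object), img)
  if (is.null(acts[[layer]])) stop("no layer named '", layer, "'")
  a <- acts[[layer]]
  m <- apply(a, c(1, 2), mean)
  m <- bilinear_resize(m, nrow(img), ncol(img))
  if (!is.null(blend_alpha)) {
    sc <- function(z) if (diff(range(z)) > 0) (z - min(z)) / diff(range(z)) else z
    m <- blend_alpha * sc(m) + (1 - blend_alpha) * sc(img)
  }
  new_attribution_map(m, "avg_feature", layer = layer)
}

# the deepest backbone path as a sequence of primitive ops, for receptive
# field interval propagation
backbone_path <- function(backbone) {
  D <- backbone$depth
  ops <- character(0)
  for (l in seq_len(D - 1)) ops <- c(ops, "conv3", "conv3", "pool2")
  ops <- c(ops, "conv3", "conv3")
  for (l in seq_len(D - 1)) ops <- c(ops, "up2", "conv3", "conv3")
  c(ops, "conv1")
}

#' Analytic receptive field of an output pixel
#'
#' Propagates the index interval of one output pixel backwards through the
#' deepest backbone path (encoder, bottleneck, decoder, head): a same-padded
#' 3x3 convolution widens the interval by one pixel on each side, 2x2
#' pooling maps `[a, b]` to `[2a, 2b + 1]`, and a 2x2 stride-2 transposed
#' convolution maps it to `[floor(a/2), floor(b/2)]`. Skip connections only
#' contribute sub-intervals of this box, so the box is the full receptive
#' field. The result is clipped to the image bounds.
#'
#' @param backbone a [backbone_config()].
#' @param output_pixel `c(row, col)`, 1-based.
#' @param image_size `c(H, W)` used for clipping.
#' @return object of class `"receptive_field"`: list with `center` and
#'   `box = c(row_min, row_max, col_min, col_max)` (inclusive bounds).
#' @export
#' @examples
#' rf <- receptive_field(backbone_config(depth = 3), c(32, 32), c(64, 64))
#' rf$box
receptive_field <- function(backbone, output_pixel, image_size) {
  stopifnot(length(output_pixel) == 2, length(image_size) == 2,
            all(output_pixel >= 1), all(output_pixel <= image_size))
  ops <- rev(backbone_path(backbone))
  lo <- output_pixel - 1  # 0-based (row, col)
  hi <- output_pixel - 1
  for (op in ops) {
    if (op == "conv3") {
      lo <- lo - 1; hi <- hi + 1
    } else if (op == "pool2") {
      lo <- 2 * lo; hi <- 2 * hi + 1
    } else if (op == "up2") {
      lo <- floor(lo / 2); hi <- floor(hi / 2)
    }  # conv1: identity
  }
  box <- c(max(lo[1] + 1, 1), min(hi[1] + 1, image_size[1]),
           max(lo[2] + 1, 1), min(hi[2] + 1, image_size[2]))
  structure(list(center = output_pixel,
                 box = c(row_min = box[1], row_max = box[2],
                         col_min = box[3], col_max = box[4])),
            class = "receptive_field")
}

#' @export
print.receptive_field <- function(x, ...) {
  cat(sprintf("<receptive_field of (%d, %d): rows %d..%d, cols %d..%d>\n",
              x$center[1], x$center[2], x$box["row_min"], x$box["row_max"],
              x$box["col_min"], x$box["col_max"]))
  invisible(x)
}

# gradient of one output pixel of one head w.r.t. the input image (analytic
# backprop); used in tests against the receptive-field box and finite
# differences
output_pixel_gradient <- function(object, input, head, pixel) {
  img <- interpret_input(object, input)
  w <- matrix(0, nrow(img), ncol(img))
  w[pixel[1], pixel[2]] <- 1
  at <- .unet_attribution(net_ptr(object), img, head, w, guided = FALSE,
                          cam_layer = "")
  at$input_grad
}
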
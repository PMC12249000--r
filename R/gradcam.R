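# Grad-CAM saliency for the malignant logit.
#
# The target layer is the network's final refined feature map (the CBAM
# output for the full variant; the depthwise-separable stack output when the
# attention stage is ablated) — the layer feeding global average pooling.

#' Core Grad-CAM map from activations and gradients
#'
#' Gradients are spatially averaged into per-channel weights; the weighted
#' activation sum is rectified and min-max normalized to `[0, 1]`. If the
#' rectified map is constant (e.g. all-zero gradients) the map is all zeros
#' rather than dividing by zero.
#'
#' @param activations numeric array `C x H x W`.
#' @param gradients numeric array `C x H x W` (gradient of the malignant
#'   logit with respect to `activations`).
#' @return H x W matrix in `[0, 1]`.
#' @export
grad_cam_map <- function(activations, gradients) {
  da <- dim(activations)
  if (!identical(da, dim(gradients)))
    cs_stop("activations and gradients must share dimensions",
            "cellsage_shape_error")
  if (length(da) != 3L || da[2] < 1L || da[3] < 1L)
    cs_stop("Grad-CAM requires a layer with spatial extent",
            "cellsage_config_error")
  alpha <- apply(gradients, 1, mean)
  cam <- matrix(0, da[2], da[3])
  for (c in seq_len(da[1])) cam <- cam + alpha[c] * activations[c, , ]
  cam <- pmax(cam, 0)
  rng <- range(cam)
  if (rng[2] - rng[1] <= 0) return(matrix(0, da[2], da[3]))
  (cam - rng[1]) / (rng[2] - rng[1])
}

#' Grad-CAM for a model and one preprocessed image
#'
#' Runs a forward pass, takes the gradient of the malignant logit with
#' respect to the final refined feature map, forms the rectified weighted
#' activation sum, and bilinearly upsamples it to input resolution.
#'
#' @param net a `cellsage_model`.
#' @param x preprocessed image, `3 x S x S` (see [preprocess_image()]).
#' @return list with `map` (S x S matrix in `[0, 1]`), `raw_map` (at feature
#'   resolution) and `logit`.
#' @export
grad_cam <- function(net, x) {
  if (length(dim(x)) == 3L) x <- array(x, c(1L, dim(x)))
  size <- net$config$input_size
  X <- bm_from_nchw(x)
  out <- net_forward(net, X, 1L, size, size, training = FALSE, keep = TRUE)
  A <- out$cache$target                     # (P x C) activation at GAP input
  H <- out$H; W <- out$W
  P <- H * W
  # d logit / d A: the head is GAP -> (identity dropout) -> linear
  dA <- matrix(rep(as.vector(net$params[["head.w"]]), each = P), P) / P
  act <- aperm(array(A, c(H, W, ncol(A))), c(3, 1, 2))
  grd <- aperm(array(dA, c(H, W, ncol(A))), c(3, 1, 2))
  raw <- grad_cam_map(act, grd)
  map <- resize_bilinear(array(raw, c(H, W, 1L)), size, size)[, , 1]
  list(map = clamp(map, 0, 1), raw_map = raw, logit = out$logit)
}

# blue (low) -> cyan -> yellow -> red (high)
heat_colormap <- function(v) {
  v <- clamp(v, 0, 1)
  r <- clamp(3 * v - 1.5, 0, 1)
  g <- clamp(1.5 - abs(3 * v - 1.5), 0, 1)
  b <- clamp(1.5 - 3 * v, 0, 1)
  cbind(r, g, b)
}

#' Render a Grad-CAM overlay
#'
#' Blends a blue-to-red heat map (red = high attention, blue = low) over the
#' raw image.
#'
#' @param image raw RGB image, H x W x 3 in `[0, 255]`.
#' @param map saliency map in `[0, 1]`, resized to the image if needed.
#' @param alpha heat-map opacity.
#' @return H x W x 3 overlay in `[0, 255]`.
#' @export
gradcam_overlay <- function(image, map, alpha = 0.45) {
  d <- dim(image)
  if (!all(dim(map) == d[1:2]))
    map <- resize_bilinear(array(map, c(dim(map), 1L)), d[1], d[2])[, , 1]
  heat <- array(heat_colormap(as.vector(map)) * 255, c(d[1], d[2], 3L))
  clamp((1 - alpha) * image + alpha * heat, 0, 255)
}
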
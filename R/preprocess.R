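# Image preparation: reference-stain appearance mapping, rescaling and
# standardization with the ImageNet channel statistics, and training-time
# augmentation. Raw images are H x W x 3 arrays in [0, 255].

#' Reference stain-appearance profile
#'
#' Per-channel mean and standard deviation of a reference image in the
#' working (CIE Lab) color space. Every image is affinely mapped so its Lab
#' channel statistics match the profile, in the Reinhard appearance-transfer
#' sense.
#'
#' @param channel_means,channel_stds numeric 3-vectors in Lab; stds must be
#'   strictly positive.
#' @param space_tag color-space identifier (only `"lab"` is implemented).
#' @return an object of class `stain_profile`.
#' @export
stain_profile <- function(channel_means, channel_stds, space_tag = "lab") {
  if (length(channel_means) != 3L || length(channel_stds) != 3L ||
      !all(is.finite(channel_means)) || !all(is.finite(channel_stds)) ||
      any(channel_stds <= 0))
    cs_stop("stain profile needs finite 3-vector means and positive stds",
            "cellsage_config_error")
  if (!identical(space_tag, "lab"))
    cs_stop("unsupported stain color space '%s'", "cellsage_config_error",
            space_tag)
  structure(list(channel_means = as.numeric(channel_means),
                 channel_stds = as.numeric(channel_stds),
                 space_tag = space_tag),
            class = "stain_profile")
}

#' Extract a stain profile from a reference image
#'
#' @param image raw RGB image, H x W x 3 in `[0, 255]`.
#' @return a [stain_profile()].
#' @export
extract_stain_profile <- function(image) {
  lab <- rgb255_to_lab(image)
  stain_profile(colMeans(lab), pmax(apply(lab, 2, stats::sd), 1e-6))
}

#' Read or write a stain profile file
#'
#' Profiles are stored as a small documented JSON file (means, stds, space
#' tag).
#'
#' @param path file path.
#' @param profile a [stain_profile()].
#' @return `read_stain_profile` returns a `stain_profile`.
#' @export
read_stain_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stain_profile(x$channel_means, x$channel_stds, x$space_tag)
}

#' @rdname read_stain_profile
#' @export
write_stain_profile <- function(profile, path) {
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' The package's default reference stain profile
#'
#' Extracted at call time from the synthetic generator's canonical reference
#' patch (fixed seed), so the repository is self-contained and carries no
#' binary reference image.
#'
#' @return a [stain_profile()].
#' @export
default_stain_profile <- function() {
  extract_stain_profile(canonical_reference_patch())
}

#' Map an image onto a reference stain appearance
#'
#' Converts the image to CIE Lab, affinely rescales each channel so its mean
#' and standard deviation equal the reference profile's, converts back to
#' sRGB and clips to the valid range. A zero-variance source channel is
#' guarded (epsilon floor), so constant patches map to the reference mean
#' rather than producing non-finite values. Deterministic, and idempotent up
#' to color-space round-trip error.
#'
#' @param image raw RGB image, H x W x 3 in `[0, 255]`.
#' @param profile a [stain_profile()].
#' @return normalized image, H x W x 3 in `[0, 255]`.
#' @export
stain_normalize <- function(image, profile) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L || d[1] < 1L || d[2] < 1L)
    cs_stop("stain_normalize expects a non-empty H x W x 3 RGB image",
            "cellsage_format_error")
  lab <- rgb255_to_lab(image)
  mu <- colMeans(lab)
  sd_ <- apply(lab, 2, stats::sd)
  n <- nrow(lab)
  if (n < 2L) sd_ <- rep(0, 3)
  scale <- profile$channel_stds / pmax(sd_, 1e-8)
  scale[sd_ < 1e-8] <- 0   # constant channel -> pinned to reference mean
  mapped <- sweep(sweep(lab, 2, mu), 2, scale, `*`)
  mapped <- sweep(mapped, 2, profile$channel_means, `+`)
  lab_to_rgb255(mapped, d[1], d[2])
}

#' Rescale and standardize an image for the network
#'
#' Pixels are divided by 255 into `[0, 1]` and standardized per channel with
#' the ImageNet statistics, mean `(0.485, 0.456, 0.406)` and standard
#' deviation `(0.229, 0.224, 0.225)`, channel order R, G, B.
#'
#' @param image raw RGB image, H x W x 3 in `[0, 255]`.
#' @return numeric array `3 x H x W`.
#' @export
rescale_standardize <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    cs_stop("rescale_standardize expects an H x W x 3 image",
            "cellsage_format_error")
  if (min(image) < 0 || max(image) > 255)
    cs_stop("pixel values outside the raw [0, 255] range",
            "cellsage_input_error")
  mean_ <- c(0.485, 0.456, 0.406)
  sd_ <- c(0.229, 0.224, 0.225)
  out <- array(0, c(3L, d[1], d[2]))
  for (c in 1:3) out[c, , ] <- (image[, , c] / 255 - mean_[c]) / sd_[c]
  out
}

#' Training-time augmentation policy
#'
#' @param max_rotation maximum absolute rotation in degrees.
#' @param hflip,vflip enable random horizontal / vertical flips.
#' @param zoom_range scaling interval (must contain 1 unless degenerate).
#' @param max_shift maximum absolute translation in pixels, each axis.
#' @param color_jitter list with relative `brightness`, `contrast`,
#'   `saturation` ranges and absolute `hue` shift.
#' @return an object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(max_rotation = 30,
                                hflip = TRUE, vflip = TRUE,
                                zoom_range = c(0.8, 1.2),
                                max_shift = 20,
                                color_jitter = list(brightness = 0.1,
                                                    contrast = 0.1,
                                                    saturation = 0.1,
                                                    hue = 0.02)) {
  if (max_rotation < 0 || max_rotation > 180)
    cs_stop("max_rotation must be within [0, 180] degrees",
            "cellsage_config_error")
  if (length(zoom_range) != 2L || zoom_range[1] > zoom_range[2] ||
      (zoom_range[1] > 1 || zoom_range[2] < 1))
    cs_stop("zoom_range must be an interval containing 1",
            "cellsage_config_error")
  if (max_shift < 0)
    cs_stop("max_shift must be >= 0", "cellsage_config_error")
  structure(list(max_rotation = max_rotation, hflip = hflip, vflip = vflip,
                 zoom_range = zoom_range, max_shift = max_shift,
                 color_jitter = color_jitter),
            class = "augmentation_policy")
}

#' An identity (no-op) augmentation policy
#' @return an `augmentation_policy` under which [augment()] returns its input.
#' @export
identity_policy <- function() {
  augmentation_policy(max_rotation = 0, hflip = FALSE, vflip = FALSE,
                      zoom_range = c(1, 1), max_shift = 0,
                      color_jitter = list(brightness = 0, contrast = 0,
                                          saturation = 0, hue = 0))
}

# sample the random draws of one augmentation; exposed for bound tests
sample_augmentation <- function(policy, draw_seed) {
  with_seed(draw_seed, list(
    rotation = stats::runif(1, -policy$max_rotation, policy$max_rotation),
    hflip = policy$hflip && stats::runif(1) < 0.5,
    vflip = policy$vflip && stats::runif(1) < 0.5,
    zoom = stats::runif(1, policy$zoom_range[1], policy$zoom_range[2]),
    shift = stats::runif(2, -policy$max_shift, policy$max_shift),
    brightness = 1 + stats::runif(1, -policy$color_jitter$brightness,
                                  policy$color_jitter$brightness),
    contrast = 1 + stats::runif(1, -policy$color_jitter$contrast,
                                policy$color_jitter$contrast),
    saturation = 1 + stats::runif(1, -policy$color_jitter$saturation,
                                  policy$color_jitter$saturation),
    hue = stats::runif(1, -policy$color_jitter$hue, policy$color_jitter$hue)
  ))
}

#' Apply one random augmentation draw
#'
#' Samples a rotation, independent horizontal/vertical flips, a zoom factor,
#' a translation, and color jitter from a generator seeded by `draw_seed`,
#' then applies the geometric part as one affine warp (bilinear
#' interpolation, reflect padding) followed by the photometric part. The same
#' `(image, policy, draw_seed)` triple always yields an identical output.
#'
#' @param image raw RGB image, H x W x 3 in `[0, 255]`.
#' @param policy an [augmentation_policy()].
#' @param draw_seed integer seed for this draw.
#' @return augmented image, H x W x 3 in `[0, 255]`.
#' @export
augment <- function(image, policy, draw_seed = 0L) {
  s <- sample_augmentation(policy, draw_seed)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  out <- image
  geometric <- s$rotation != 0 || s$zoom != 1 || any(s$shift != 0) ||
    s$hflip || s$vflip
  if (geometric) {
    th <- s$rotation * pi / 180
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    yo <- rep(seq_len(H), times = W) - cy
    xo <- rep(seq_len(W), each = H) - cx
    # inverse map: undo shift, then inverse rotation+zoom, then flips
    ys <- yo - s$shift[1]; xs <- xo - s$shift[2]
    ct <- cos(-th); st <- sin(-th)
    yi <- (ct * ys - st * xs) / s$zoom
    xi <- (st * ys + ct * xs) / s$zoom
    if (s$vflip) yi <- -yi
    if (s$hflip) xi <- -xi
    sm <- bilinear_sample(image, yi + cy, xi + cx, pad = "reflect")
    out <- array(sm, c(H, W, 3L))
  }
  cj <- s[c("brightness", "contrast", "saturation")]
  if (any(unlist(cj) != 1) || s$hue != 0) {
    m <- img_to_pixmat(out) / 255
    m <- clamp(m * s$brightness, 0, 1)
    mu <- mean(m)
    m <- clamp((m - mu) * s$contrast + mu, 0, 1)
    gray <- m %*% matrix(c(0.299, 0.587, 0.114), 3, 1)
    m <- clamp(gray[, 1] + (m - gray[, 1]) * s$saturation, 0, 1)
    if (s$hue != 0) {
      hsv <- rgb_to_hsv_mat(m)
      hsv[, 1] <- (hsv[, 1] + s$hue) %% 1
      m <- hsv_to_rgb_mat(hsv)
    }
    out <- pixmat_to_img(m * 255, H, W)
  }
  out
}

#' Full preprocessing pipeline
#'
#' `stain_normalize` then (in training mode) `augment`, then bilinear resize
#' to the target resolution, then [rescale_standardize()]. Evaluation mode
#' omits augmentation and is a pure function of its inputs.
#'
#' @param image raw RGB image, H x W x 3 in `[0, 255]`.
#' @param profile a [stain_profile()] (or `NULL` to skip stain mapping).
#' @param target_size output resolution in pixels.
#' @param train_mode logical; apply augmentation.
#' @param draw_seed augmentation seed (training mode only).
#' @param policy an [augmentation_policy()]; default the published one.
#' @return numeric array `3 x target_size x target_size`.
#' @export
preprocess_image <- function(image, profile, target_size = 224L,
                             train_mode = FALSE, draw_seed = 0L,
                             policy = augmentation_policy()) {
  x <- if (is.null(profile)) image else stain_normalize(image, profile)
  if (train_mode) x <- augment(x, policy, draw_seed)
  if (dim(x)[1] != target_size || dim(x)[2] != target_size)
    x <- resize_bilinear(x, target_size, target_size)
  rescale_standardize(clamp(x, 0, 255))
}
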
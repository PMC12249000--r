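# Color-space helpers. Raw images are H x W x 3 arrays in [0, 255], channel
# order R, G, B. The stain-appearance working space is CIE Lab (D65), reached
# through grDevices::convertColor.

img_to_pixmat <- function(img) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L)
    cs_stop("expected an H x W x 3 RGB image", "cellsage_format_error")
  matrix(img, d[1] * d[2], 3L)
}

pixmat_to_img <- function(m, H, W) array(m, c(H, W, 3L))

rgb255_to_lab <- function(img) {
  m <- img_to_pixmat(img) / 255
  grDevices::convertColor(clamp(m, 0, 1), from = "sRGB", to = "Lab")
}

lab_to_rgb255 <- function(lab, H, W) {
  m <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  pixmat_to_img(clamp(m, 0, 1) * 255, H, W)
}

# Numeric HSV <-> RGB on [0,1] matrices (grDevices::hsv returns strings, so
# the inverse is written out; standard sextant formulas).
rgb_to_hsv_mat <- function(m) {
  t(grDevices::rgb2hsv(t(m), maxColorValue = 1))
}

hsv_to_rgb_mat <- function(m) {
  h <- (m[, 1] %% 1) * 6; s <- clamp(m[, 2], 0, 1); v <- clamp(m[, 3], 0, 1)
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}
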
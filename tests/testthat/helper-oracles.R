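# Independent explicit-loop oracles and small fixture builders.
# These deliberately avoid every vectorized path in the package: plain scalar
# loops, zero padding written out, pair counting for AUC.

# "same"-padded 2D convolution, explicit loops. x: C x H x W array,
# w: k x k x Cin x Cout, b: length Cout. Returns Cout x Hout x Wout.
oracle_conv2d <- function(x, w, b, stride = 1L) {
  k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  H <- dim(x)[2]; W <- dim(x)[3]
  p <- (k - 1) %/% 2
  Hout <- (H + 2 * p - k) %/% stride + 1
  Wout <- (W + 2 * p - k) %/% stride + 1
  out <- array(0, c(cout, Hout, Wout))
  for (co in seq_len(cout)) for (i in seq_len(Hout)) for (j in seq_len(Wout)) {
    acc <- b[co]
    for (ci in seq_len(cin)) for (di in seq_len(k)) for (dj in seq_len(k)) {
      yi <- (i - 1) * stride + di - p
      xj <- (j - 1) * stride + dj - p
      if (yi >= 1 && yi <= H && xj >= 1 && xj <= W)
        acc <- acc + x[ci, yi, xj] * w[di, dj, ci, co]
    }
    out[co, i, j] <- acc
  }
  out
}

# depthwise convolution oracle: w is k x k x C
oracle_dwconv <- function(x, w, b, stride = 1L) {
  C <- dim(x)[1]
  out <- NULL
  for (c in seq_len(C)) {
    wc <- array(w[, , c], c(dim(w)[1], dim(w)[2], 1, 1))
    oc <- oracle_conv2d(array(x[c, , ], c(1, dim(x)[2], dim(x)[3])), wc,
                        b[c], stride)
    if (is.null(out)) out <- array(0, c(C, dim(oc)[2], dim(oc)[3]))
    out[c, , ] <- oc[1, , ]
  }
  out
}

# AUC by exhaustive pair counting (ties count one half)
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# tiny architecture used throughout the fast tests
tiny_model_config <- function(...) {
  model_config(input_size = 16L, mscfe_branch_channels = 2L,
               stage_widths = c(4L, 8L), blocks_per_stage = 1L,
               cbam_reduction_ratio = 2L, dropout_rate = 0.1, ...)
}

# manifest fixture: patients per class with fake image paths
make_index <- function(n_benign, n_malignant, images_per_patient = 2L) {
  rows <- list()
  mk <- function(cl, n, tag, subtype) {
    for (p in seq_len(n)) for (j in seq_len(images_per_patient)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        image_path = sprintf("%s%02d_%d.png", tag, p, j),
        patient_id = sprintf("%s%02d", tag, p),
        class_label = cl, subtype = subtype,
        magnification = c(40L, 100L, 200L, 400L)[(j - 1L) %% 4L + 1L])
    }
  }
  mk("benign", n_benign, "B", "fibroadenoma")
  mk("malignant", n_malignant, "M", "ductal_carcinoma")
  df <- do.call(rbind, rows)
  class(df) <- c("dataset_index", "data.frame")
  df
}

write_index_csv <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  path
}

# feature-map fixture with reproducible values
random_fm <- function(C, H, W, role = "input_x", seed = 1) {
  set.seed(seed)
  feature_map(array(rnorm(C * H * W), c(C, H, W)), role)
}
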
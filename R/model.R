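# The network: multi-scale feature extractor -> depthwise-separable stack ->
# CBAM -> global average pool -> dropout -> single-logit head.

#' Build the network
#'
#' Instantiates the architecture described by `config` with He-normal
#' initialized convolution/linear weights (biases zero, batch-norm scale 1 /
#' shift 0). Identical `(config, seed)` pairs produce bitwise-identical
#' weights.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `cellsage_model`.
#' @export
build_model <- function(config, seed = 1L) {
  validate_model_config(config)
  b <- config$mscfe_branch_channels
  cin <- config$input_channels
  concat <- 3L * b
  widths <- config$stage_widths
  params <- list()
  with_seed(seed, {
    if (config$variant == "no_mscfe") {
      params[["mscfe.single.w"]] <- he_normal(c(3L, 3L, cin, concat), cin * 9)
      params[["mscfe.single.b"]] <- numeric(concat)
    } else {
      for (i in seq_along(config$mscfe_kernels)) {
        k <- config$mscfe_kernels[i]
        params[[sprintf("mscfe.b%d.w", i)]] <-
          he_normal(c(k, k, cin, b), cin * k * k)
        params[[sprintf("mscfe.b%d.b", i)]] <- numeric(b)
      }
    }
    C <- concat
    for (s in seq_along(widths)) for (blk in seq_len(config$blocks_per_stage)) {
      pre <- sprintf("stage%d.block%d", s, blk)
      params[[paste0(pre, ".dw.w")]] <- he_normal(c(3L, 3L, C), 9)
      params[[paste0(pre, ".dw.b")]] <- numeric(C)
      params[[paste0(pre, ".bn.gamma")]] <- rep(1, C)
      params[[paste0(pre, ".bn.beta")]] <- numeric(C)
      w <- widths[s]
      params[[paste0(pre, ".pw.w")]] <- matrix(stats::rnorm(C * w, 0, sqrt(2 / C)), C, w)
      params[[paste0(pre, ".pw.b")]] <- numeric(w)
      C <- w
    }
    if (config$variant != "no_cbam") {
      hid <- C %/% config$cbam_reduction_ratio
      params[["cbam.mlp.w1"]] <- matrix(stats::rnorm(C * hid, 0, sqrt(2 / C)), C, hid)
      params[["cbam.mlp.b1"]] <- numeric(hid)
      params[["cbam.mlp.w2"]] <- matrix(stats::rnorm(hid * C, 0, sqrt(2 / hid)), hid, C)
      params[["cbam.mlp.b2"]] <- numeric(C)
      sk <- config$spatial_kernel
      params[["cbam.sp.w"]] <- he_normal(c(sk, sk, 2L, 1L), 2 * sk * sk)
      params[["cbam.sp.b"]] <- numeric(1)
    }
    params[["head.w"]] <- matrix(stats::rnorm(C, 0, sqrt(2 / C)), C, 1)
    params[["head.b"]] <- numeric(1)
  })
  state <- list()
  C <- concat
  for (s in seq_along(widths)) for (blk in seq_len(config$blocks_per_stage)) {
    pre <- sprintf("stage%d.block%d", s, blk)
    state[[paste0(pre, ".bn.mean")]] <- numeric(C)
    state[[paste0(pre, ".bn.var")]] <- rep(1, C)
    C <- widths[s]
  }
  structure(list(config = config, params = params, state = state, seed = seed),
            class = "cellsage_model")
}

#' Build an ablation variant
#'
#' `"no_cbam"` removes the attention stage entirely (the depthwise-separable
#' output feeds the head); `"no_mscfe"` replaces the three parallel branches
#' with a single 3x3 convolution producing the same total channel count so
#' every downstream shape is unchanged; `"full"` equals [build_model()].
#'
#' @param config a [model_config()] (its own `variant` field is overridden).
#' @param variant `"full"`, `"no_cbam"` or `"no_mscfe"`.
#' @param seed initialization seed.
#' @return a `cellsage_model`.
#' @export
build_variant <- function(config, variant, seed = 1L) {
  if (!is.character(variant) || length(variant) != 1L ||
      !variant %in% c("full", "no_cbam", "no_mscfe"))
    cs_stop("unknown variant label '%s'", "cellsage_config_error",
            paste(variant, collapse = ","))
  cfg <- config
  cfg$variant <- variant
  validate_model_config(cfg)
  build_model(cfg, seed)
}

#' @export
print.cellsage_model <- function(x, ...) {
  n <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<cellsage_model variant=%s, %s parameters, input %d^2>\n",
              x$config$variant, format(n, big.mark = ","), x$config$input_size))
  invisible(x)
}

# ---- full forward / backward ---------------------------------------------

net_forward <- function(net, X, N, H, W, training = FALSE, keep = FALSE) {
  cfg <- net$config
  p <- net$params
  cache <- list(N = N)
  # multi-scale feature extractor
  if (cfg$variant == "no_mscfe") {
    cv <- conv2d_fwd(X, N, H, W, p[["mscfe.single.w"]], p[["mscfe.single.b"]],
                     cfg$mscfe_stride, keep)
    r <- relu_fwd(cv$Y)
    X <- r$Y; H <- cv$H; W <- cv$W
    if (keep) cache$mscfe <- list(single = cv$cache, relu = list(r$cache))
  } else {
    outs <- vector("list", 3L); caches <- vector("list", 3L); rl <- vector("list", 3L)
    for (i in 1:3) {
      k <- cfg$mscfe_kernels[i]
      cv <- conv2d_fwd(X, N, H, W, p[[sprintf("mscfe.b%d.w", i)]],
                       p[[sprintf("mscfe.b%d.b", i)]], cfg$mscfe_stride, keep)
      r <- relu_fwd(cv$Y)
      outs[[i]] <- r$Y; caches[[i]] <- cv$cache; rl[[i]] <- r$cache
      Ho <- cv$H; Wo <- cv$W
    }
    X <- do.call(cbind, outs); H <- Ho; W <- Wo
    if (keep) cache$mscfe <- list(branches = caches, relu = rl)
  }
  # depthwise-separable stack
  stages <- list()
  for (s in seq_along(cfg$stage_widths)) for (blk in seq_len(cfg$blocks_per_stage)) {
    pre <- sprintf("stage%d.block%d", s, blk)
    stride <- if (blk == 1L) 2L else 1L
    dw <- dwconv_fwd(X, N, H, W, p[[paste0(pre, ".dw.w")]],
                     p[[paste0(pre, ".dw.b")]], stride, keep)
    bn <- bn_fwd(dw$Y, p[[paste0(pre, ".bn.gamma")]], p[[paste0(pre, ".bn.beta")]],
                 net$state[[paste0(pre, ".bn.mean")]],
                 net$state[[paste0(pre, ".bn.var")]], training)
    if (training) {
      net$state[[paste0(pre, ".bn.mean")]] <- bn$run_mean
      net$state[[paste0(pre, ".bn.var")]] <- bn$run_var
    }
    r1 <- relu_fwd(bn$Y)
    pw_y <- r1$Y %*% p[[paste0(pre, ".pw.w")]] +
      rep(p[[paste0(pre, ".pw.b")]], each = nrow(r1$Y))
    r2 <- relu_fwd(pw_y)
    dr <- dropout_fwd(r2$Y, cfg$dropout_rate, training)
    if (keep) stages[[pre]] <- list(dw = dw$cache, bn = bn$cache, r1 = r1$cache,
                                    pw_in = r1$Y, r2 = r2$cache, drop = dr$cache,
                                    pre = pre)
    X <- dr$Y; H <- dw$H; W <- dw$W
  }
  cache$stages <- stages
  cache$fdwb <- if (keep) X else NULL
  C <- ncol(X); P <- H * W
  # CBAM
  if (cfg$variant != "no_cbam") {
    avg <- gap_fwd(X, N, P)
    mx <- gmp_fwd(X, N, P)
    mlp <- function(v) {
      h_pre <- v %*% p[["cbam.mlp.w1"]] + rep(p[["cbam.mlp.b1"]], each = N)
      h <- pmax(h_pre, 0)
      list(z = h %*% p[["cbam.mlp.w2"]] + rep(p[["cbam.mlp.b2"]], each = N),
           h = h, mask = h_pre > 0)
    }
    m_mx <- mlp(mx$Y); m_avg <- mlp(avg)
    gate <- sigmoid(m_mx$z + m_avg$z)                 # N x C
    Gexp <- gate[img_groups(N, P), , drop = FALSE]
    Fp <- X * Gexp
    cp <- chanpool_fwd(Fp)
    pooled <- cbind(cp$mx, cp$avg)                    # (N*P) x 2
    sp <- conv2d_fwd(pooled, N, H, W, p[["cbam.sp.w"]], p[["cbam.sp.b"]], 1L, keep)
    smap <- sigmoid(sp$Y[, 1])
    Fpp <- Fp * smap
    if (keep) cache$cbam <- list(X = X, avg = avg, mx = mx, m_mx = m_mx,
                                 m_avg = m_avg, gate = gate, Fp = Fp, cp = cp,
                                 sp = sp$cache, smap = smap, P = P)
    X <- Fpp
  }
  cache$target <- if (keep) X else NULL   # final refined map (Grad-CAM layer)
  # head
  g <- gap_fwd(X, N, P)
  dr <- dropout_fwd(g, cfg$dropout_rate, training)
  logit <- as.vector(dr$Y %*% p[["head.w"]]) + p[["head.b"]]
  if (keep) cache$head <- list(gap_in_dims = c(H = H, W = W, C = C), g = g,
                               drop = dr$cache, gpost = dr$Y)
  list(logit = logit, prob = sigmoid(logit), cache = cache, H = H, W = W,
       state = net$state)
}

net_backward <- function(net, cache, dlogit) {
  cfg <- net$config
  p <- net$params
  g <- list()
  N <- cache$N
  hd <- cache$head
  H <- hd$gap_in_dims[["H"]]; W <- hd$gap_in_dims[["W"]]
  P <- H * W
  g[["head.w"]] <- crossprod(hd$gpost, matrix(dlogit, ncol = 1))
  g[["head.b"]] <- sum(dlogit)
  dg <- matrix(dlogit, ncol = 1) %*% t(p[["head.w"]])       # N x C
  dg <- dropout_bwd(hd$drop, dg)
  dX <- gap_bwd(dg, N, P)
  g$d_target <- dX                                           # grad at refined map
  if (cfg$variant != "no_cbam") {
    cb <- cache$cbam
    dFp <- dX * cb$smap
    dsmap <- rowSums(dX * cb$Fp)
    dz_sp <- dsmap * cb$smap * (1 - cb$smap)
    spb <- conv2d_bwd(cb$sp, matrix(dz_sp, ncol = 1))
    g[["cbam.sp.w"]] <- spb$dW
    g[["cbam.sp.b"]] <- spb$db
    dpool <- spb$dX                                          # (N*P) x 2
    # channel pools backward
    R <- N * P
    dFp_pool <- matrix(0, R, ncol(cb$Fp))
    dFp_pool[cbind(seq_len(R), cb$cp$argmax)] <- dpool[, 1]
    dFp_pool <- dFp_pool + dpool[, 2] / ncol(cb$Fp)
    dFp <- dFp + dFp_pool
    # gate application backward
    Gexp <- cb$gate[img_groups(N, P), , drop = FALSE]
    dXpre <- dFp * Gexp
    dgate <- rowsum(dFp * cb$X, img_groups(N, P))            # N x C
    dzsum <- dgate * cb$gate * (1 - cb$gate)
    mlp_bwd <- function(m, vin, dz) {
      dW2 <- crossprod(m$h, dz)
      db2 <- colSums(dz)
      dh <- (dz %*% t(p[["cbam.mlp.w2"]])) * m$mask
      dW1 <- crossprod(vin, dh)
      db1 <- colSums(dh)
      list(dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2,
           dv = dh %*% t(p[["cbam.mlp.w1"]]))
    }
    b_mx <- mlp_bwd(cb$m_mx, cb$mx$Y, dzsum)
    b_avg <- mlp_bwd(cb$m_avg, cb$avg, dzsum)
    g[["cbam.mlp.w1"]] <- b_mx$dW1 + b_avg$dW1
    g[["cbam.mlp.b1"]] <- b_mx$db1 + b_avg$db1
    g[["cbam.mlp.w2"]] <- b_mx$dW2 + b_avg$dW2
    g[["cbam.mlp.b2"]] <- b_mx$db2 + b_avg$db2
    dXpre <- dXpre + gmp_bwd(cb$mx$argmax, b_mx$dv, N, P) +
      gap_bwd(b_avg$dv, N, P)
    dX <- dXpre
  }
  # depthwise-separable stack, reversed
  for (key in rev(names(cache$stages))) {
    st <- cache$stages[[key]]
    pre <- st$pre
    dX <- dropout_bwd(st$drop, dX)
    dX <- relu_bwd(st$r2, dX)
    g[[paste0(pre, ".pw.w")]] <- crossprod(st$pw_in, dX)
    g[[paste0(pre, ".pw.b")]] <- colSums(dX)
    dX <- dX %*% t(p[[paste0(pre, ".pw.w")]])
    dX <- relu_bwd(st$r1, dX)
    bb <- bn_bwd(st$bn, dX)
    g[[paste0(pre, ".bn.gamma")]] <- bb$dgamma
    g[[paste0(pre, ".bn.beta")]] <- bb$dbeta
    db <- dwconv_bwd(st$dw, bb$dX)
    g[[paste0(pre, ".dw.w")]] <- db$dW
    g[[paste0(pre, ".dw.b")]] <- db$db
    dX <- db$dX
  }
  # extractor
  if (cfg$variant == "no_mscfe") {
    dX <- relu_bwd(cache$mscfe$relu[[1]], dX)
    cb <- conv2d_bwd(cache$mscfe$single, dX)
    g[["mscfe.single.w"]] <- cb$dW
    g[["mscfe.single.b"]] <- cb$db
  } else {
    b <- cfg$mscfe_branch_channels
    for (i in 1:3) {
      cols <- (i - 1L) * b + seq_len(b)
      db_ <- relu_bwd(cache$mscfe$relu[[i]], dX[, cols, drop = FALSE])
      cb <- conv2d_bwd(cache$mscfe$branches[[i]], db_)
      g[[sprintf("mscfe.b%d.w", i)]] <- cb$dW
      g[[sprintf("mscfe.b%d.b", i)]] <- cb$db
    }
  }
  g
}

#' Run the network on a batch of preprocessed images
#'
#' @param net a `cellsage_model`.
#' @param x numeric array `C x H x W` or `N x C x H x W` of preprocessed
#'   (standardized) images matching the configured input size and channels.
#' @param training logical; evaluation mode (the default) is deterministic
#'   (dropout is identity, batch norm uses running statistics).
#' @return numeric vector of N malignancy probabilities in (0, 1).
#' @export
model_forward <- function(net, x, training = FALSE) {
  if (length(dim(x)) == 3L) x <- array(x, c(1L, dim(x)))
  d <- dim(x)
  cfg <- net$config
  if (d[2] != cfg$input_channels || d[3] != cfg$input_size || d[4] != cfg$input_size)
    cs_stop("expected input %d x %d x %d, got %d x %d x %d",
            "cellsage_shape_error", cfg$input_channels, cfg$input_size,
            cfg$input_size, d[2], d[3], d[4])
  X <- bm_from_nchw(x)
  out <- net_forward(net, X, d[1], d[3], d[4], training = training, keep = FALSE)
  out$prob
}

#' @export
predict.cellsage_model <- function(object, newdata, ...) {
  model_forward(object, newdata, training = FALSE)
}

# ---- module-level operations (the published building blocks) --------------

#' Multi-scale convolutional feature extraction
#'
#' Applies three parallel convolutions (kernel sizes given largest-first,
#' shared stride, "same" zero padding) to the same input and concatenates the
#' outputs along the channel axis in kernel order.
#'
#' @param x a [feature_map()] with role `"input_x"`.
#' @param params list with `weights` (list of three `k x k x Cin x Cout`
#'   arrays), `bias` (list of three vectors, or `NULL`s), `stride`, and
#'   `activation` (logical; apply ReLU after each branch).
#' @return a `feature_map` with role `"f_mscfe"`.
#' @export
mscfe_forward <- function(x, params) {
  d <- fm_dims(x)
  cin <- dim(params$weights[[1]])[3]
  if (d$C != cin)
    cs_stop("input has %d channels but branch weights expect %d",
            "cellsage_shape_error", d$C, cin)
  X <- bm_from_nchw(x$values)
  outs <- list()
  for (i in seq_along(params$weights)) {
    cv <- conv2d_fwd(X, d$N, d$H, d$W, params$weights[[i]],
                     params$bias[[i]], params$stride)
    outs[[i]] <- if (isTRUE(params$activation)) pmax(cv$Y, 0) else cv$Y
    Ho <- cv$H; Wo <- cv$W
  }
  Y <- do.call(cbind, outs)
  feature_map(bm_to_nchw(Y, d$N, ncol(Y), Ho, Wo), "f_mscfe")
}

#' Depthwise-separable block forward
#'
#' Per block: depthwise 3x3 convolution, batch normalization, ReLU, pointwise
#' 1x1 convolution, ReLU, dropout (identity in evaluation mode). Blocks are
#' applied in sequence.
#'
#' @param f a `feature_map` (role `"f_mscfe"` upstream).
#' @param params list with `blocks` (each: `dw_w` `3x3xC` array, `dw_b`,
#'   `gamma`, `beta`, `run_mean`, `run_var`, `pw_w` `Cin x Cout` matrix,
#'   `pw_b`, `stride`), plus optional `activation` (default TRUE),
#'   `dropout_rate` (default 0), `training` (default FALSE), `eps`
#'   (batch-norm epsilon, default 1e-5).
#' @return a `feature_map` with role `"f_dwb"`.
#' @export
dwb_forward <- function(f, params) {
  d <- fm_dims(f)
  act <- !isFALSE(params$activation)
  eps <- if (is.null(params$eps)) 1e-5 else params$eps
  training <- isTRUE(params$training)
  rate <- if (is.null(params$dropout_rate)) 0 else params$dropout_rate
  X <- bm_from_nchw(f$values)
  H <- d$H; W <- d$W
  for (bl in params$blocks) {
    dw <- dwconv_fwd(X, d$N, H, W, bl$dw_w, bl$dw_b, bl$stride)
    bn <- bn_fwd(dw$Y, bl$gamma, bl$beta, bl$run_mean, bl$run_var,
                 training, eps = eps)
    h <- if (act) pmax(bn$Y, 0) else bn$Y
    y <- h %*% bl$pw_w + rep(bl$pw_b, each = nrow(h))
    y <- if (act) pmax(y, 0) else y
    X <- dropout_fwd(y, rate, training)$Y
    H <- dw$H; W <- dw$W
  }
  feature_map(bm_to_nchw(X, d$N, ncol(X), H, W), "f_dwb")
}

#' Channel attention
#'
#' Global max pooling and global average pooling over the spatial dimensions
#' give two channel descriptors; both pass through the SAME shared two-layer
#' perceptron (C -> C/r -> C, ReLU between), the outputs are summed and
#' squashed with a sigmoid into a per-channel gate which rescales the input.
#'
#' @param f a `feature_map` (role `"f_dwb"`).
#' @param params list with `w1` (`C x hid`), `b1`, `w2` (`hid x C`), `b2`.
#' @return list with `channel_map` (vector of length C for a single image,
#'   else N x C matrix, entries strictly in (0,1)) and `f_prime` (a
#'   `feature_map`).
#' @export
channel_attention <- function(f, params) {
  d <- fm_dims(f)
  if (d$C != nrow(params$w1))
    cs_stop("attention MLP expects %d channels, got %d",
            "cellsage_config_error", nrow(params$w1), d$C)
  X <- bm_from_nchw(f$values)
  P <- d$H * d$W
  avg <- gap_fwd(X, d$N, P)
  mx <- gmp_fwd(X, d$N, P)$Y
  mlp <- function(v) {
    h <- pmax(v %*% params$w1 + rep(params$b1, each = d$N), 0)
    h %*% params$w2 + rep(params$b2, each = d$N)
  }
  gate <- sigmoid(mlp(mx) + mlp(avg))
  Fp <- X * gate[img_groups(d$N, P), , drop = FALSE]
  list(channel_map = if (d$N == 1L) as.vector(gate) else gate,
       f_prime = feature_map(bm_to_nchw(Fp, d$N, d$C, d$H, d$W), "f_prime"))
}

#' Spatial attention
#'
#' Channel-wise max and average pooling produce two H x W maps which are
#' concatenated, convolved with a single odd-sized kernel ("same" padding)
#' and squashed with a sigmoid into a per-pixel gate applied to the input.
#'
#' @param f_prime a `feature_map` (role `"f_prime"`).
#' @param params list with `w` (`k x k x 2 x 1` array) and `b` (length-1).
#' @return list with `spatial_map` (H x W matrix for a single image, entries
#'   strictly in (0,1); N x H x W array otherwise) and `f_double_prime`.
#' @export
spatial_attention <- function(f_prime, params) {
  d <- fm_dims(f_prime)
  X <- bm_from_nchw(f_prime$values)
  cp <- chanpool_fwd(X)
  pooled <- cbind(cp$mx, cp$avg)
  cv <- conv2d_fwd(pooled, d$N, d$H, d$W, params$w, params$b, 1L)
  smap <- sigmoid(cv$Y[, 1])
  Fpp <- X * smap
  map <- if (d$N == 1L) matrix(smap, d$H, d$W)
         else aperm(array(smap, c(d$H, d$W, d$N)), c(3, 1, 2))
  list(spatial_map = map,
       f_double_prime = feature_map(bm_to_nchw(Fpp, d$N, d$C, d$H, d$W),
                                    "f_double_prime"))
}

# ---- checkpoints ----------------------------------------------------------

encode_array <- function(a) {
  list(dim = dim(a) %||% length(a),
       data = jsonlite::base64_enc(writeBin(as.numeric(a), raw(),
                                            size = 8, endian = "little")))
}

decode_array <- function(e) {
  v <- readBin(jsonlite::base64_dec(e$data), "numeric", n = prod(unlist(e$dim)),
               size = 8, endian = "little")
  d <- unlist(e$dim)
  if (length(d) > 1L) array(v, d) else v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing JSON archives holding the configuration
#' and every weight array (base64-encoded little-endian IEEE-754 doubles), so
#' loading restores bit-identical evaluation-mode behavior.
#'
#' @param net a `cellsage_model`.
#' @param path file path (`.json`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a `cellsage_model`.
#' @export
save_checkpoint <- function(net, path) {
  obj <- list(
    format = "cellsage-checkpoint-v1",
    config = unclass(net$config),
    params = lapply(net$params, encode_array),
    state = lapply(net$state, encode_array)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "cellsage-checkpoint-v1"))
    cs_stop("%s is not a cellsage checkpoint", "cellsage_format_error", path)
  cfgl <- obj$config
  cfgl$mscfe_kernels <- unlist(cfgl$mscfe_kernels)
  cfgl$stage_widths <- unlist(cfgl$stage_widths)
  cfg <- do.call(model_config, cfgl)
  params <- lapply(obj$params, decode_array)
  # pointwise / MLP / head weights are matrices
  state <- lapply(obj$state, function(e) as.vector(decode_array(e)))
  structure(list(config = cfg, params = params, state = state, seed = NA),
            class = "cellsage_model")
}
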
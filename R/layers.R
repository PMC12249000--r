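# Neural-network primitives on base R + BLAS.
#
# Batch activation layout ("bm", batch matrix): a (N*P) x C numeric matrix,
# P = H*W spatial positions stored column-major (row index fastest), images
# stacked image-major (rows 1..P are image 1). This makes pointwise
# convolutions single BLAS calls and lets k x k convolutions be computed as
# k^2 shifted gathers, each an (N*P x C) %*% (C x Cout) product. Every
# forward has a hand-derived backward; gradients are exact (verified against
# finite differences and explicit-loop oracles in the test suite).

# ---- layout helpers -------------------------------------------------------

# N x C x H x W array -> batch matrix
bm_from_nchw <- function(arr) {
  d <- dim(arr)  # N, C, H, W
  m <- aperm(arr, c(3, 4, 1, 2))               # H, W, N, C
  dim(m) <- c(d[3] * d[4], d[1], d[2])         # P, N, C
  m <- aperm(m, c(1, 2, 3))
  out <- matrix(0, d[1] * d[3] * d[4], d[2])
  P <- d[3] * d[4]
  for (n in seq_len(d[1])) out[(n - 1) * P + seq_len(P), ] <- m[, n, ]
  out
}

bm_to_nchw <- function(X, N, C, H, W) {
  P <- H * W
  arr <- array(0, c(N, C, H, W))
  for (n in seq_len(N)) {
    block <- X[(n - 1) * P + seq_len(P), , drop = FALSE]  # P x C
    arr[n, , , ] <- aperm(array(block, c(H, W, C)), c(3, 1, 2))
  }
  arr
}

# ---- convolution indexing -------------------------------------------------

# Precompute gather indices for a k x k convolution with "same" zero padding
# (pad = (k-1)/2) and the given stride. Returns spatial indices into the
# padded plane for each of the k^2 offsets.
conv_index <- function(H, W, k, stride) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Hout <- (H + 2L * p - k) %/% stride + 1L
  Wout <- (W + 2L * p - k) %/% stride + 1L
  oi <- rep(seq_len(Hout), times = Wout)       # output row index
  oj <- rep(seq_len(Wout), each = Hout)
  base_i <- 1L + (oi - 1L) * stride
  base_j <- 1L + (oj - 1L) * stride
  k2 <- k * k
  Ispat <- matrix(0L, Hout * Wout, k2)
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    jj <- dj * k + di + 1L
    Ispat[, jj] <- (base_i + di) + (base_j + dj - 1L) * Hp
  }
  # interior positions of the unpadded image inside the padded plane
  ii <- rep(seq_len(H), times = W) + p
  jj <- rep(seq_len(W), each = H) + p
  intr <- ii + (jj - 1L) * Hp
  list(Hp = Hp, Wp = Wp, Hout = Hout, Wout = Wout, Ispat = Ispat,
       intr = intr, k = k, stride = stride)
}

pad_bm <- function(X, N, H, W, ci) {
  P <- H * W; Pp <- ci$Hp * ci$Wp
  Xp <- matrix(0, N * Pp, ncol(X))
  rows <- as.vector(outer(ci$intr, (seq_len(N) - 1L) * Pp, "+"))
  Xp[rows, ] <- X
  Xp
}

unpad_bm <- function(dXp, N, H, W, ci) {
  Pp <- ci$Hp * ci$Wp
  rows <- as.vector(outer(ci$intr, (seq_len(N) - 1L) * Pp, "+"))
  dXp[rows, , drop = FALSE]
}

gather_rows <- function(ci, N) {
  Pout <- ci$Hout * ci$Wout
  Pp <- ci$Hp * ci$Wp
  ci$Ispat[rep(seq_len(Pout), N), , drop = FALSE] +
    rep((seq_len(N) - 1L) * Pp, each = Pout)
}

# ---- standard convolution -------------------------------------------------

# weights: array(k, k, Cin, Cout); bias: length Cout (or NULL)
conv2d_fwd <- function(X, N, H, W, weights, bias, stride, keep_cache = FALSE) {
  k <- dim(weights)[1]; Cin <- dim(weights)[3]; Cout <- dim(weights)[4]
  if (ncol(X) != Cin)
    cs_stop("convolution expects %d input channels, got %d",
            "cellsage_shape_error", Cin, ncol(X))
  ci <- conv_index(H, W, k, stride)
  Xp <- pad_bm(X, N, H, W, ci)
  RI <- gather_rows(ci, N)
  Wm <- matrix(weights, k * k * Cin, Cout)
  Y <- matrix(0, N * ci$Hout * ci$Wout, Cout)
  for (j in seq_len(k * k)) {
    Wj <- matrix(Wm[(seq_len(Cin) - 1L) * (k * k) + j, ], Cin, Cout)
    Y <- Y + Xp[RI[, j], , drop = FALSE] %*% Wj
  }
  if (!is.null(bias)) Y <- Y + rep(bias, each = nrow(Y))
  out <- list(Y = Y, H = ci$Hout, W = ci$Wout)
  if (keep_cache) out$cache <- list(Xp = Xp, RI = RI, ci = ci, N = N,
                                    Hin = H, Win = W, weights = weights)
  out
}

conv2d_bwd <- function(cache, dY) {
  w <- cache$weights
  k <- dim(w)[1]; Cin <- dim(w)[3]; Cout <- dim(w)[4]
  RI <- cache$RI; Xp <- cache$Xp
  dW <- array(0, dim(w))
  dXp <- matrix(0, nrow(Xp), Cin)
  Wm <- matrix(w, k * k * Cin, Cout)
  for (j in seq_len(k * k)) {
    G <- Xp[RI[, j], , drop = FALSE]                    # (N*Pout) x Cin
    dWj <- crossprod(G, dY)                             # Cin x Cout
    di <- (j - 1L) %% k + 1L; dj <- (j - 1L) %/% k + 1L

    dW[di, dj, , ] <- dWj
    Wj <- matrix(Wm[(seq_len(Cin) - 1L) * (k * k) + j, ], Cin, Cout)
    contrib <- dY %*% t(Wj)                             # (N*Pout) x Cin
    rows <- RI[, j]
    dXp[rows, ] <- dXp[rows, , drop = FALSE] + contrib
  }
  db <- colSums(dY)
  dX <- unpad_bm(dXp, cache$N, cache$Hin, cache$Win, cache$ci)
  list(dW = dW, db = db, dX = dX)
}

# ---- depthwise convolution ------------------------------------------------

# weights: array(k, k, C); one spatial filter per channel
dwconv_fwd <- function(X, N, H, W, weights, bias, stride, keep_cache = FALSE) {
  k <- dim(weights)[1]; C <- dim(weights)[3]
  if (ncol(X) != C)
    cs_stop("depthwise convolution expects %d channels, got %d",
            "cellsage_shape_error", C, ncol(X))
  ci <- conv_index(H, W, k, stride)
  Xp <- pad_bm(X, N, H, W, ci)
  RI <- gather_rows(ci, N)
  Wm <- matrix(weights, k * k, C)  # rows: offset (di fastest), cols: channel
  R <- nrow(RI)
  Y <- matrix(0, R, C)
  for (j in seq_len(k * k))
    Y <- Y + Xp[RI[, j], , drop = FALSE] * rep(Wm[j, ], each = R)
  if (!is.null(bias)) Y <- Y + rep(bias, each = R)
  out <- list(Y = Y, H = ci$Hout, W = ci$Wout)
  if (keep_cache) out$cache <- list(Xp = Xp, RI = RI, ci = ci, N = N,
                                    Hin = H, Win = W, weights = weights)
  out
}

dwconv_bwd <- function(cache, dY) {
  w <- cache$weights
  k <- dim(w)[1]; C <- dim(w)[3]
  RI <- cache$RI; Xp <- cache$Xp
  Wm <- matrix(w, k * k, C)
  R <- nrow(dY)
  dWm <- matrix(0, k * k, C)
  dXp <- matrix(0, nrow(Xp), C)
  for (j in seq_len(k * k)) {
    G <- Xp[RI[, j], , drop = FALSE]
    dWm[j, ] <- colSums(G * dY)
    contrib <- dY * rep(Wm[j, ], each = R)
    rows <- RI[, j]
    dXp[rows, ] <- dXp[rows, , drop = FALSE] + contrib
  }
  list(dW = array(dWm, dim(w)), db = colSums(dY),
       dX = unpad_bm(dXp, cache$N, cache$Hin, cache$Win, cache$ci))
}

# ---- batch normalization --------------------------------------------------

bn_fwd <- function(X, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5) {
  R <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = R)
    v <- colMeans(xc * xc)
    new_mean <- (1 - momentum) * run_mean + momentum * mu
    new_var <- (1 - momentum) * run_var +
      momentum * v * if (R > 1) R / (R - 1) else 1
  } else {
    mu <- run_mean; v <- run_var
    xc <- X - rep(mu, each = R)
    new_mean <- run_mean; new_var <- run_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(invstd, each = R)
  Y <- xhat * rep(gamma, each = R) + rep(beta, each = R)
  list(Y = Y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                           training = training),
       run_mean = new_mean, run_var = new_var)
}

bn_bwd <- function(cache, dY) {
  R <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(cache$gamma, each = R)
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dX <- (dxhat - rep(s1 / R, each = R) - xhat * rep(s2 / R, each = R)) *
      rep(cache$invstd, each = R)
  } else {
    dX <- dxhat * rep(cache$invstd, each = R)
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- activations / dropout ------------------------------------------------

relu_fwd <- function(X) list(Y = pmax(X, 0), cache = X > 0)
relu_bwd <- function(cache, dY) dY * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, cache = NULL))
  keep <- 1 - rate
  mask <- (matrix(stats::runif(length(X)), nrow(X)) < keep) / keep
  list(Y = X * mask, cache = mask)
}
dropout_bwd <- function(cache, dY) if (is.null(cache)) dY else dY * cache

# ---- pooling --------------------------------------------------------------

img_groups <- function(N, P) rep(seq_len(N), each = P)

# global average pool: (N*P) x C -> N x C
gap_fwd <- function(X, N, P) rowsum(X, img_groups(N, P)) / P
gap_bwd <- function(dG, N, P) dG[rep(seq_len(N), each = P), , drop = FALSE] / P

# global max pool with argmax (for backward routing)
gmp_fwd <- function(X, N, P) {
  C <- ncol(X)
  arr <- array(X, c(P, N, C))          # valid: rows ordered p fastest, n outer
  Xr <- matrix(arr, P, N * C)
  am <- max.col(t(Xr), ties.method = "first")
  vals <- Xr[cbind(am, seq_len(N * C))]
  list(Y = matrix(vals, N, C), argmax = am)
}
gmp_bwd <- function(argmax, dG, N, P) {
  C <- ncol(dG)
  dX <- matrix(0, N * P, C)
  q <- seq_len(N * C)
  n <- (q - 1L) %% N + 1L
  c <- (q - 1L) %/% N + 1L
  dX[cbind((n - 1L) * P + argmax, c)] <- as.vector(dG)
  dX
}

# channel-wise pools for spatial attention: (N*P) x C -> vectors length N*P
chanpool_fwd <- function(X) {
  am <- max.col(X, ties.method = "first")
  list(mx = X[cbind(seq_len(nrow(X)), am)], avg = rowMeans(X), argmax = am)
}

# ---- initialization -------------------------------------------------------

he_normal <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}
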
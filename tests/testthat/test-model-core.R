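# model_core: construction, module forwards vs explicit-loop oracles,
# attention properties, variants, checkpoints.

test_that("build_model is seeded, validated, and shaped as configured", {
  cfg <- tiny_model_config()
  n1 <- build_model(cfg, seed = 17)
  n2 <- build_model(cfg, seed = 17)
  expect_identical(n1$params, n2$params)
  n3 <- build_model(cfg, seed = 18)
  expect_false(identical(n1$params, n3$params))
  expect_error(model_config(dropout_rate = 1.0), "dropout_rate",
               class = "cellsage_config_error")
  expect_error(model_config(mscfe_kernels = c(7L, 4L, 3L)),
               class = "cellsage_config_error")
  expect_error(model_config(stage_widths = c(64L, 100L),
                            cbam_reduction_ratio = 16L),
               class = "cellsage_config_error")
  # head input width equals the last stage width
  ref <- build_model(reference_config(), seed = 1)
  expect_equal(nrow(ref$params[["head.w"]]),
               tail(reference_config()$stage_widths, 1))
})

test_that("mscfe_forward: channel/stride arithmetic, linearity, conv oracle", {
  # published geometry: 3 x 224 x 224 in, 32-channel branches, stride 2
  set.seed(4)
  mk_params <- function(b, cin, stride, act = TRUE, ones = FALSE) {
    ws <- lapply(c(7L, 5L, 3L), function(k) {
      if (ones) array(1, c(k, k, cin, b))
      else array(rnorm(k * k * cin * b, 0, 0.1), c(k, k, cin, b))
    })
    list(weights = ws, bias = lapply(ws, function(w) numeric(b)),
         stride = stride, activation = act)
  }
  x <- feature_map(array(rnorm(3 * 224 * 224), c(3, 224, 224)), "input_x")
  out <- mscfe_forward(x, mk_params(32L, 3L, 2L))
  expect_equal(dim(out$values), c(1L, 96L, 112L, 112L))
  # zero input with zero biases -> zero output
  z <- feature_map(array(0, c(3, 8, 8)), "input_x")
  zo <- mscfe_forward(z, mk_params(2L, 3L, 1L))
  expect_true(all(zo$values == 0))
  # 1 x 8 x 8, width 1, stride 1, all-ones kernels, no activation ==
  # sliding-window sum oracle
  set.seed(7)
  xs <- array(rnorm(64), c(1, 8, 8))
  pr <- mk_params(1L, 1L, 1L, act = FALSE, ones = TRUE)
  got <- mscfe_forward(feature_map(xs, "input_x"), pr)
  for (i in 1:3) {
    want <- oracle_conv2d(xs, pr$weights[[i]], 0, 1L)
    expect_equal(got$values[1, i, , ], want[1, , ], tolerance = 1e-10)
  }
  # channel mismatch -> shape error
  expect_error(mscfe_forward(feature_map(array(0, c(2, 8, 8)), "input_x"),
                             mk_params(1L, 3L, 1L)),
               class = "cellsage_shape_error")
})

test_that("dwb_forward: identity composition, oracle equivalence, width contract", {
  # centered-impulse depthwise + identity pointwise + identity BN == identity
  C <- 3L
  imp <- array(0, c(3, 3, C)); imp[2, 2, ] <- 1
  blk <- list(dw_w = imp, dw_b = numeric(C), gamma = rep(1, C),
              beta = numeric(C), run_mean = numeric(C), run_var = rep(1, C),
              pw_w = diag(C), pw_b = numeric(C), stride = 1L)
  set.seed(11)
  f <- feature_map(array(abs(rnorm(C * 5 * 5)), c(C, 5, 5)), "f_mscfe")
  out <- dwb_forward(f, list(blocks = list(blk), activation = FALSE, eps = 0))
  expect_equal(out$values, f$values, tolerance = 1e-12)
  # 2-channel 3x3 fixed kernels: DW then PW vs explicit loops
  set.seed(12)
  x2 <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  dw <- array(rnorm(18, 0, 0.5), c(3, 3, 2)); dwb <- rnorm(2)
  pw <- matrix(rnorm(8, 0, 0.5), 2, 4); pwb <- rnorm(4)
  blk2 <- list(dw_w = dw, dw_b = dwb, gamma = rep(1, 2), beta = numeric(2),
               run_mean = numeric(2), run_var = rep(1, 2),
               pw_w = pw, pw_b = pwb, stride = 1L)
  got <- dwb_forward(feature_map(x2, "f_mscfe"),
                     list(blocks = list(blk2), activation = FALSE, eps = 0))
  mid <- oracle_dwconv(x2, dw, dwb, 1L)
  want <- array(0, c(4, 3, 3))
  for (co in 1:4) for (i in 1:3) for (j in 1:3)
    want[co, i, j] <- sum(mid[, i, j] * pw[, co]) + pwb[co]
  expect_equal(got$values[1, , , ], want, tolerance = 1e-10)
  # output width follows the block regardless of spatial size
  got2 <- dwb_forward(random_fm(2, 7, 9, "f_mscfe", 3),
                      list(blocks = list(blk2)))
  expect_equal(dim(got2$values)[2], 4L)
})

test_that("channel_attention: symmetry, sigma(0) = 1/2, hand-arithmetic oracle", {
  # all channels identical -> all attention weights equal
  base <- matrix(rnorm(16), 4, 4)
  eqv <- array(0, c(3, 4, 4))
  for (c in 1:3) eqv[c, , ] <- base
  f_eq <- feature_map(eqv, "f_dwb")
  pr <- list(w1 = matrix(0.3, 3, 1), b1 = 0.1,
             w2 = matrix(0.2, 1, 3), b2 = rep(-0.1, 3))
  ca <- channel_attention(f_eq, pr)
  expect_equal(max(ca$channel_map) - min(ca$channel_map), 0, tolerance = 1e-12)
  # zero MLP -> every weight 0.5, F' = f / 2
  f <- random_fm(4, 3, 3, "f_dwb", 21)
  zr <- list(w1 = matrix(0, 4, 2), b1 = numeric(2),
             w2 = matrix(0, 2, 4), b2 = numeric(4))
  ca0 <- channel_attention(f, zr)
  expect_equal(unname(ca0$channel_map), rep(0.5, 4))
  expect_equal(ca0$f_prime$values, 0.5 * f$values, tolerance = 1e-12)
  # 2-channel 2x2, fixed weights: scalar arithmetic done independently
  xv <- array(c(1, -2, 3, 0.5, -1, 2, 0, 4), c(2, 2, 2))
  w1 <- matrix(c(0.5, -0.3, 0.2, 0.4), 2, 2)  # C=2 -> hid=2
  b1 <- c(0.1, -0.2)
  w2 <- matrix(c(-0.4, 0.6, 0.3, -0.5), 2, 2)
  b2 <- c(0.05, -0.05)
  mxp <- c(max(xv[1, , ]), max(xv[2, , ]))
  avp <- c(mean(xv[1, , ]), mean(xv[2, , ]))
  mlp <- function(v) {
    h <- pmax(c(v %*% w1) + b1, 0)
    c(h %*% w2) + b2
  }
  gate <- 1 / (1 + exp(-(mlp(mxp) + mlp(avp))))
  got <- channel_attention(feature_map(xv, "f_dwb"),
                           list(w1 = w1, b1 = b1, w2 = w2, b2 = b2))
  expect_equal(unname(got$channel_map), unname(gate), tolerance = 1e-12)
  expect_equal(got$f_prime$values[1, 1, , ], xv[1, , ] * gate[1],
               tolerance = 1e-12)
  expect_equal(got$f_prime$values[1, 2, , ], xv[2, , ] * gate[2],
               tolerance = 1e-12)
})

test_that("spatial_attention: constancy, sigmoid contract, conv oracle", {
  k <- 7L
  set.seed(31)
  w <- array(rnorm(k * k * 2, 0, 0.2), c(k, k, 2, 1))
  b <- 0.1
  # spatially constant input -> constant map everywhere (zero padding sees
  # the same 2-channel constant through the pinned padding only in the
  # interior; with per-pixel identical pooled maps the interior is constant)
  cf <- feature_map(array(rep(c(1, 2, 3), times = 81), c(3, 9, 9)), "f_prime")
  sa <- spatial_attention(cf, list(w = w, b = b))
  interior <- sa$spatial_map[4:6, 4:6]
  expect_equal(max(interior) - min(interior), 0, tolerance = 1e-12)
  # bounds + shape on random input
  f <- random_fm(3, 9, 9, "f_prime", 32)
  sa2 <- spatial_attention(f, list(w = w, b = b))
  expect_equal(dim(sa2$spatial_map), c(9L, 9L))
  expect_true(all(sa2$spatial_map > 0 & sa2$spatial_map < 1))
  # oracle: channel max/avg pooling by loops, 7x7 conv oracle, scalar sigmoid
  xv <- f$values[1, , , ]
  mx <- apply(xv, c(2, 3), max)
  av <- apply(xv, c(2, 3), mean)
  pooled <- array(0, c(2, 9, 9)); pooled[1, , ] <- mx; pooled[2, , ] <- av
  want <- 1 / (1 + exp(-oracle_conv2d(pooled, w, b, 1L)[1, , ]))
  expect_equal(sa2$spatial_map, want, tolerance = 1e-5)
  # F'' = map * F'
  expect_equal(sa2$f_double_prime$values[1, 2, , ], xv[2, , ] * sa2$spatial_map,
               tolerance = 1e-12)
})

test_that("forward: probability contract and bitwise determinism", {
  cfg <- tiny_model_config()
  net <- build_model(cfg, seed = 5)
  set.seed(6)
  x <- array(rnorm(5 * 3 * 16 * 16), c(5, 3, 16, 16))
  p1 <- model_forward(net, x)
  expect_length(p1, 5L)
  expect_true(all(p1 > 0 & p1 < 1))
  p2 <- model_forward(net, x)
  expect_identical(p1, p2)
  expect_error(model_forward(net, array(0, c(2, 3, 8, 8))),
               class = "cellsage_shape_error")
})

test_that("attention boundedness and attenuation on random cases", {
  for (s in 1:6) {
    set.seed(100 + s)
    C <- sample(2:4, 1) * 2L
    H <- sample(3:7, 1)
    f <- feature_map(array(rnorm(C * H * H, 0, 2), c(C, H, H)), "f_dwb")
    hid <- C %/% 2L
    pr <- list(w1 = matrix(rnorm(C * hid), C, hid), b1 = rnorm(hid),
               w2 = matrix(rnorm(hid * C), hid, C), b2 = rnorm(C))
    ca <- channel_attention(f, pr)
    expect_true(all(ca$channel_map > 0 & ca$channel_map < 1))
    expect_lte(max(abs(ca$f_prime$values)), max(abs(f$values)))
    sw <- array(rnorm(49 * 2), c(7, 7, 2, 1))
    sa <- spatial_attention(ca$f_prime, list(w = sw, b = rnorm(1)))
    expect_true(all(sa$spatial_map > 0 & sa$spatial_map < 1))
    expect_lte(max(abs(sa$f_double_prime$values)),
               max(abs(ca$f_prime$values)))
  }
})

test_that("variants: definitions, shapes and parameter ordering", {
  cfg <- tiny_model_config()
  full <- build_model(cfg, seed = 9)
  full2 <- build_variant(cfg, "full", seed = 9)
  expect_identical(full$params, full2$params)
  nc <- build_variant(cfg, "no_cbam", seed = 9)
  nm <- build_variant(cfg, "no_mscfe", seed = 9)
  expect_lt(enumerate_parameters(nc), enumerate_parameters(full))
  expect_lt(enumerate_parameters(nm), enumerate_parameters(full))
  # no_mscfe single conv still emits 3 * branch channels (96 under default)
  ref_nm <- build_model(reference_config("no_mscfe"), seed = 1)
  expect_equal(dim(ref_nm$params[["mscfe.single.w"]])[4], 96L)
  # downstream shapes unchanged: forward works for all variants
  set.seed(10)
  x <- array(rnorm(2 * 3 * 16 * 16), c(2, 3, 16, 16))
  for (net in list(full, nc, nm)) {
    p <- model_forward(net, x)
    expect_true(all(p > 0 & p < 1) && length(p) == 2L)
  }
  expect_error(build_variant(cfg, "no_attention"),
               class = "cellsage_config_error")
})

test_that("checkpoints restore bit-identical evaluation behavior", {
  cfg <- tiny_model_config()
  net <- build_model(cfg, seed = 23)
  f <- tempfile(fileext = ".json")
  save_checkpoint(net, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, net$params)
  set.seed(24)
  x <- array(rnorm(3 * 3 * 16 * 16), c(3, 3, 16, 16))
  expect_identical(model_forward(net, x), model_forward(back, x))
  expect_error(load_checkpoint(write_model_config(cfg, tempfile())),
               class = "cellsage_format_error")
})

test_that("config files round-trip", {
  cfg <- tiny_model_config(variant = "no_cbam")
  f <- tempfile(fileext = ".json")
  write_model_config(cfg, f)
  expect_equal(read_model_config(f), cfg)
})
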
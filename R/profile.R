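# Analytic efficiency profiling.
#
# Counting conventions (pinned by the printed baseline budgets):
#   parameters — conv: Cout*Cin*k^2/groups (+ Cout bias where present);
#                batch norm: 2C (affine); linear: in*out + out.
#   MACs       — conv: Hout*Wout*Cout*Cin*k^2/groups; linear: in*out.
#                Normalization, pooling, activations and the element-wise
#                attention multiplications are excluded; one MAC is reported
#                as one FLOP.

new_profile_builder <- function(input_size) {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$H <- input_size
  env$input_size <- input_size
  env$add <- function(name, params, macs) {
    env$rows[[length(env$rows) + 1L]] <-
      data.frame(layer = name, params = params, macs = macs)
  }
  env$conv <- function(name, cin, cout, k, stride = 1L, groups = 1L,
                       bias = TRUE, bn = FALSE, spatial = TRUE) {
    Hout <- if (spatial) (env$H + 2 * ((k - 1) %/% 2) - k) %/% stride + 1L else 1L
    p <- cout * cin * k^2 / groups + if (bias) cout else 0
    if (bn) p <- p + 2 * cout
    m <- (if (spatial) Hout^2 else 1) * cout * cin * k^2 / groups
    env$add(name, p, m)
    if (spatial) env$H <- Hout
    invisible(NULL)
  }
  env$linear <- function(name, cin, cout, bias = TRUE) {
    env$add(name, cin * cout + if (bias) cout else 0, cin * cout)
  }
  env
}

finish_profile <- function(env) {
  tab <- do.call(rbind, env$rows)
  structure(list(per_layer = tab,
                 total_params = sum(tab$params),
                 total_macs = sum(tab$macs),
                 input_size = env$input_size),
            class = "profile_report")
}

#' @export
print.profile_report <- function(x, ...) {
  cat(sprintf("Profile at %d x %d input\n", x$input_size, x$input_size))
  tab <- x$per_layer
  tab$params <- format(tab$params, big.mark = ",")
  tab$macs <- format(tab$macs, big.mark = ",")
  print(tab, row.names = FALSE, right = FALSE)
  cat(sprintf("total: %s params (%.2f M), %s MACs (%.3f G)\n",
              format(x$total_params, big.mark = ","), x$total_params / 1e6,
              format(x$total_macs, big.mark = ","), x$total_macs / 1e9))
  invisible(x)
}

profile_cellsage <- function(config, input_size = config$input_size) {
  validate_model_config(config)
  pb <- new_profile_builder(input_size)
  b <- config$mscfe_branch_channels
  cin <- config$input_channels
  concat <- 3L * b
  if (config$variant == "no_mscfe") {
    pb$conv("extractor.single3x3", cin, concat, 3L, config$mscfe_stride)
  } else {
    H0 <- pb$H
    for (i in seq_along(config$mscfe_kernels)) {
      pb$H <- H0  # parallel branches share the input resolution
      k <- config$mscfe_kernels[i]
      pb$conv(sprintf("mscfe.branch%dx%d", k, k), cin, b, k, config$mscfe_stride)
    }
  }
  C <- concat
  for (s in seq_along(config$stage_widths)) {
    w <- config$stage_widths[s]
    for (blk in seq_len(config$blocks_per_stage)) {
      pre <- sprintf("stage%d.block%d", s, blk)
      stride <- if (blk == 1L) 2L else 1L
      pb$conv(paste0(pre, ".dw3x3"), C, C, 3L, stride, groups = C)
      pb$add(paste0(pre, ".bn"), 2 * C, 0)
      pb$conv(paste0(pre, ".pw1x1"), C, w, 1L)
      C <- w
    }
  }
  if (config$variant != "no_cbam") {
    hid <- C %/% config$cbam_reduction_ratio
    # the shared MLP is invoked twice (max- and average-pooled descriptors)
    pb$add("cbam.mlp.shared", C * hid + hid + hid * C + C,
           2 * (C * hid + hid * C))
    sk <- config$spatial_kernel
    pb$conv(sprintf("cbam.spatial%dx%d", sk, sk), 2L, 1L, sk)
  }
  pb$linear("head.linear", C, 1L)
  finish_profile(pb)
}

#' Analytic parameter count
#'
#' Computes per-layer parameter counts in closed form from the architecture
#' description (convolution: `Cout*Cin*k^2/groups + Cout`; batch norm: `2C`;
#' linear: `in*out + out`). For an instantiated network the analytic total
#' equals the enumerated weight total exactly.
#'
#' @param x a [model_config()] or a `cellsage_model`.
#' @return a `profile_report` with `per_layer`, `total_params`, `total_macs`,
#'   `input_size`.
#' @export
count_parameters <- function(x) {
  cfg <- if (inherits(x, "cellsage_model")) x$config else x
  profile_cellsage(cfg)
}

#' Analytic multiply-accumulate count
#'
#' @param x a [model_config()] or a `cellsage_model`.
#' @param input_size input resolution in pixels (height = width).
#' @return a `profile_report`.
#' @export
count_macs <- function(x, input_size = NULL) {
  cfg <- if (inherits(x, "cellsage_model")) x$config else x
  profile_cellsage(cfg, input_size %||% cfg$input_size)
}

#' Enumerate the instantiated weight total
#'
#' Sums the lengths of every weight/bias/affine array actually held by the
#' network, as the exact cross-check for [count_parameters()].
#'
#' @param net a `cellsage_model`.
#' @return integer total.
#' @export
enumerate_parameters <- function(net) {
  sum(vapply(net$params, length, numeric(1)))
}

# ---- baseline profiling oracles -------------------------------------------

#' Analytic profiles of standard baseline architectures
#'
#' Layer tables of MobileNetV2 (width 1.0) and EfficientNet-B0, both with
#' the standard 1000-class ImageNet head and no pretrained weights, under the
#' same counting conventions as [count_parameters()] / [count_macs()]. They
#' exist to validate the counters: the parameter totals reproduce the
#' published reference-implementation figures exactly (3,504,872 and
#' 5,288,548).
#'
#' @param input_size input resolution (default 224).
#' @return a `profile_report`.
#' @export
profile_mobilenet_v2 <- function(input_size = 224L) {
  pb <- new_profile_builder(input_size)
  pb$conv("stem", 3L, 32L, 3L, 2L, bias = FALSE, bn = TRUE)
  cin <- 32L
  cfg <- list(c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2), c(6, 64, 4, 2),
              c(6, 96, 3, 1), c(6, 160, 3, 2), c(6, 320, 1, 1))
  bi <- 0L
  for (gcfg in cfg) {
    t <- gcfg[1]; cout <- gcfg[2]; n <- gcfg[3]; s <- gcfg[4]
    for (i in seq_len(n)) {
      bi <- bi + 1L
      stride <- if (i == 1L) s else 1L
      hid <- cin * t
      nm <- sprintf("block%02d", bi)
      if (t != 1) pb$conv(paste0(nm, ".expand"), cin, hid, 1L, bias = FALSE, bn = TRUE)
      pb$conv(paste0(nm, ".dw"), hid, hid, 3L, stride, groups = hid,
              bias = FALSE, bn = TRUE)
      pb$conv(paste0(nm, ".project"), hid, cout, 1L, bias = FALSE, bn = TRUE)
      cin <- cout
    }
  }
  pb$conv("head.conv", cin, 1280L, 1L, bias = FALSE, bn = TRUE)
  pb$linear("classifier", 1280L, 1000L)
  finish_profile(pb)
}

#' @rdname profile_mobilenet_v2
#' @export
profile_efficientnet_b0 <- function(input_size = 224L) {
  pb <- new_profile_builder(input_size)
  pb$conv("stem", 3L, 32L, 3L, 2L, bias = FALSE, bn = TRUE)
  cin <- 32L
  # expand ratio, kernel, out channels, repeats, stride; SE ratio 0.25 of the
  # block input channels
  cfg <- list(c(1, 3, 16, 1, 1), c(6, 3, 24, 2, 2), c(6, 5, 40, 2, 2),
              c(6, 3, 80, 3, 2), c(6, 5, 112, 3, 1), c(6, 5, 192, 4, 2),
              c(6, 3, 320, 1, 1))
  bi <- 0L
  for (gcfg in cfg) {
    t <- gcfg[1]; k <- gcfg[2]; cout <- gcfg[3]; n <- gcfg[4]; s <- gcfg[5]
    for (i in seq_len(n)) {
      bi <- bi + 1L
      stride <- if (i == 1L) s else 1L
      hid <- cin * t
      se <- max(1L, round(cin * 0.25))
      nm <- sprintf("block%02d", bi)
      if (t != 1) pb$conv(paste0(nm, ".expand"), cin, hid, 1L, bias = FALSE, bn = TRUE)
      pb$conv(paste0(nm, ".dw"), hid, hid, k, stride, groups = hid,
              bias = FALSE, bn = TRUE)
      pb$conv(paste0(nm, ".se.reduce"), hid, se, 1L, bias = TRUE, spatial = FALSE)
      pb$conv(paste0(nm, ".se.expand"), se, hid, 1L, bias = TRUE, spatial = FALSE)
      pb$conv(paste0(nm, ".project"), hid, cout, 1L, bias = FALSE, bn = TRUE)
      cin <- cout
    }
  }
  pb$conv("head.conv", cin, 1280L, 1L, bias = FALSE, bn = TRUE)
  pb$linear("classifier", 1280L, 1000L)
  finish_profile(pb)
}
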
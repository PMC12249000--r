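#' @keywords internal
"_PACKAGE"

# Condition helper: all package errors carry class "cellsage_error" plus a
# specific subclass so callers/tests can discriminate without string matching.
cs_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "cellsage_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package operations never perturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    cs_stop("seed must be a single finite number", "cellsage_config_error")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a stream of sub-seeds from a master seed, kept within 32-bit range.
derive_seeds <- function(seed, n) with_seed(seed, sample.int(.Machine$integer.max - 1L, n))

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 1

#' Bilinear resampling of an image array
#'
#' Samples `img` (H x W x C numeric array) at fractional coordinates using
#' bilinear interpolation. Coordinates outside the image are handled by the
#' chosen padding: `"edge"` clamps, `"reflect"` mirrors about the border.
#'
#' @param img numeric array H x W x C.
#' @param ys,xs numeric vectors (same length) of row/column sample positions
#'   (1-based, fractional allowed).
#' @param pad `"edge"` or `"reflect"`.
#' @return matrix length(ys) x C of sampled values.
#' @keywords internal
bilinear_sample <- function(img, ys, xs, pad = "reflect") {
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  fold <- function(v, n) {
    if (n == 1L) return(rep(1, length(v)))
    if (pad == "edge") return(clamp(v, 1, n))
    # reflect about pixel centers: period 2(n-1)
    per <- 2 * (n - 1)
    v <- abs(v - 1) %% per
    ifelse(v > (n - 1), per - v, v) + 1
  }
  ys <- fold(ys, H); xs <- fold(xs, W)
  y0 <- clamp(floor(ys), 1, H); x0 <- clamp(floor(xs), 1, W)
  y1 <- clamp(y0 + 1, 1, H);    x1 <- clamp(x0 + 1, 1, W)
  wy <- ys - y0; wx <- xs - x0
  out <- matrix(0, length(ys), C)
  for (c in seq_len(C)) {
    pl <- img[, , c]
    out[, c] <- (1 - wy) * (1 - wx) * pl[cbind(y0, x0)] +
      (1 - wy) * wx * pl[cbind(y0, x1)] +
      wy * (1 - wx) * pl[cbind(y1, x0)] +
      wy * wx * pl[cbind(y1, x1)]
  }
  out
}

#' Resize an image with bilinear interpolation
#'
#' @param img numeric array H x W x C.
#' @param out_h,out_w target size in pixels.
#' @return numeric array out_h x out_w x C.
#' @export
resize_bilinear <- function(img, out_h, out_w = out_h) {
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  sy <- H / out_h; sx <- W / out_w
  yc <- (seq_len(out_h) - 0.5) * sy + 0.5
  xc <- (seq_len(out_w) - 0.5) * sx + 0.5
  ys <- rep(yc, times = out_w)
  xs <- rep(xc, each = out_h)
  sm <- bilinear_sample(img, ys, xs, pad = "edge")
  array(sm, c(out_h, out_w, C))
}
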
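# Minimal PNG codec (8-bit RGB, color type 2) on base R.
#
# No PNG package is available in the target environment, so the two PNG
# features this package needs -- writing synthetic patches and reading them
# back -- are implemented directly: zlib streams come from memCompress /
# memDecompress (RFC 1950), CRC32 is computed here. The writer always emits
# filter type 0; the reader understands all five standard filters.

crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L)
        bitwXor(-306674912L, bitwShiftR(c, 1L))  # 0xEDB88320 as signed
      else bitwShiftR(c, 1L)
    }
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(raw_bytes) {
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(raw_bytes)
  for (i in seq_along(b)) {
    idx <- bitwAnd(bitwXor(crc, b[i]), 255L)
    crc <- bitwXor(crc32_table[idx + 1], bitwShiftR(crc, 8L))
  }
  bitwXor(crc, -1L)
}

u32_raw <- function(x) {
  # unsigned 32-bit big-endian from a (possibly negative) signed int or double
  if (x < 0) x <- x + 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_raw(length(data)), body, u32_raw(crc32(body)))
}

#' Write an 8-bit RGB PNG file
#'
#' @param img numeric array H x W x 3 with values in `[0, 255]` (rounded to
#'   integers on write).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L)
    cs_stop("write_png expects an H x W x 3 array", "cellsage_format_error")
  H <- d[1]; W <- d[2]
  px <- as.integer(round(clamp(img, 0, 255)))
  # scanlines: filter byte 0 + RGB triplets row-major
  arr <- array(px, d)
  rgb <- aperm(arr, c(3, 2, 1))             # C, W, H -> per-row byte order
  rows <- matrix(as.raw(rgb), nrow = 3L * W)  # one column per row of image
  scan <- rbind(matrix(as.raw(0L), 1L, H), rows)
  idat <- memCompress(as.vector(scan), type = "gzip")
  ihdr <- c(u32_raw(W), u32_raw(H), as.raw(c(8L, 2L, 0L, 0L, 0L)))
  out <- c(
    as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", idat),
    png_chunk("IEND", raw(0))
  )
  writeBin(out, path)
  invisible(path)
}

paeth <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  ifelse(pa <= pb & pa <= pc, a, ifelse(pb <= pc, b, c))
}

#' Read an 8-bit RGB PNG file
#'
#' Supports non-interlaced 8-bit RGB (color type 2) images, i.e. the files
#' this package writes plus any standard encoder's output in that format.
#'
#' @param path PNG file path.
#' @return numeric array H x W x 3 with values in `[0, 255]`.
#' @export
read_png <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 8 || !identical(bytes[1:8],
      as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))))
    cs_stop("%s is not a PNG file", "cellsage_format_error", path)
  pos <- 9L; idat <- raw(0); W <- H <- NA_integer_
  u32 <- function(i) sum(as.integer(bytes[i:(i + 3)]) * c(16777216, 65536, 256, 1))
  repeat {
    len <- u32(pos)
    type <- rawToChar(bytes[(pos + 4):(pos + 7)])
    data <- if (len > 0) bytes[(pos + 8):(pos + 7 + len)] else raw(0)
    if (type == "IHDR") {
      W <- u32(pos + 8); H <- u32(pos + 12)
      depth <- as.integer(data[9]); ctype <- as.integer(data[10])
      interlace <- as.integer(data[13])
      if (depth != 8L || ctype != 2L || interlace != 0L)
        cs_stop("only non-interlaced 8-bit RGB PNG is supported",
                "cellsage_format_error")
    } else if (type == "IDAT") idat <- c(idat, data)
    else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  scan <- memDecompress(idat, type = "gzip")
  stride <- 3L * W
  out <- matrix(0L, stride, H)
  prev <- integer(stride)
  offs <- 1L
  for (r in seq_len(H)) {
    ft <- as.integer(scan[offs])
    cur <- as.integer(scan[(offs + 1L):(offs + stride)])
    left <- function(v) c(0L, 0L, 0L, v[seq_len(stride - 3L)])
    cur <- switch(as.character(ft),
      "0" = cur,
      "2" = (cur + prev) %% 256L,
      "1" = { # sub: sequential in pixels, vector within a pixel triplet
        for (i in 4:stride) cur[i] <- (cur[i] + cur[i - 3L]) %% 256L
        cur
      },
      "3" = {
        for (i in seq_len(stride)) {
          a <- if (i > 3L) cur[i - 3L] else 0L
          cur[i] <- (cur[i] + (a + prev[i]) %/% 2L) %% 256L
        }
        cur
      },
      "4" = {
        for (i in seq_len(stride)) {
          a <- if (i > 3L) cur[i - 3L] else 0L
          cc <- if (i > 3L) prev[i - 3L] else 0L
          cur[i] <- (cur[i] + paeth(a, prev[i], cc)) %% 256L
        }
        cur
      },
      cs_stop("unsupported PNG filter type %d", "cellsage_format_error", ft)
    )
    out[, r] <- cur
    prev <- cur
    offs <- offs + stride + 1L
  }
  aperm(array(as.numeric(out), c(3L, W, H)), c(3, 2, 1))
}
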
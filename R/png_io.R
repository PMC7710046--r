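# Minimal PNG codec (8-bit, non-interlaced). Base R ships zlib via
# memCompress/memDecompress (which emit/accept zlib streams despite the
# "gzip" type label), so no imaging package is needed. The writer always
# emits filter-0 RGB rows, which makes output byte-deterministic -- equal
# pixel arrays give equal files.

crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(c, 1L))  # 0xEDB88320
      else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (v in b) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   crc32_table[bitwAnd(bitwXor(crc, v), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

u32be <- function(x) {
  # unsigned big-endian from a (possibly negative) 32-bit pattern
  if (x < 0) x <- x + 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256,
           x %% 256))
}

png_chunk <- function(type, data = raw(0)) {
  payload <- c(charToRaw(type), data)
  c(u32be(length(data)), payload, u32be(crc32(payload)))
}

#' Write an 8-bit RGB PNG
#'
#' @param rgb numeric array `h x w x 3` with values in `[0, 1]`, row 1 at the
#'   top of the image.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_png <- function(rgb, file) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  px <- as.raw(pmin(pmax(round(rgb * 255), 0), 255))
  dim(px) <- dim(rgb)
  # interleave channels row-major with a leading filter-0 byte per row
  rowbytes <- aperm(px, c(3L, 2L, 1L))  # channel-fastest, then x, then y
  dim(rowbytes) <- c(3L * w, h)
  scan <- matrix(as.raw(0L), nrow = 1L + 3L * w, ncol = h)
  scan[-1L, ] <- rowbytes
  dim(scan) <- NULL
  ihdr <- c(u32be(w), u32be(h), as.raw(c(8L, 2L, 0L, 0L, 0L)))
  body <- c(charToRaw("\x89PNG\r\n\x1a\n"),
            png_chunk("IHDR", ihdr),
            png_chunk("IDAT", memCompress(scan, "gzip")),
            png_chunk("IEND"))
  writeBin(body, file)
  invisible(file)
}

paeth <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  ifelse(pa <= pb & pa <= pc, a, ifelse(pb <= pc, b, c))
}

#' Read an 8-bit non-interlaced PNG
#'
#' Supports grayscale, RGB, palette and alpha variants at bit depth 8 (the
#' formats the package itself and common AFM image exports produce); alpha is
#' discarded. Returns an `h x w x 3` array in `[0, 1]`, row 1 at the top.
#'
#' @param file path to the PNG.
#' @return numeric array `h x w x 3`.
#' @export
read_png <- function(file) {
  b <- readBin(file, "raw", file.size(file))
  if (length(b) < 8L ||
      !identical(b[1:8], charToRaw("\x89PNG\r\n\x1a\n")))
    stop("not a PNG file: ", file)
  i <- 9L
  idat <- list(); ihdr <- NULL; plte <- NULL; trns <- NULL
  while (i + 7L <= length(b)) {
    len <- sum(as.integer(b[i:(i + 3L)]) * c(16777216, 65536, 256, 1))
    typ <- rawToChar(b[(i + 4L):(i + 7L)])
    dat <- if (len > 0L) b[(i + 8L):(i + 7L + len)] else raw(0)
    if (typ == "IHDR") ihdr <- dat
    else if (typ == "PLTE") plte <- dat
    else if (typ == "IDAT") idat[[length(idat) + 1L]] <- dat
    else if (typ == "IEND") break
    i <- i + 12L + len
  }
  if (is.null(ihdr) || length(idat) == 0L) stop("malformed PNG: ", file)
  w <- sum(as.integer(ihdr[1:4]) * c(16777216, 65536, 256, 1))
  h <- sum(as.integer(ihdr[5:8]) * c(16777216, 65536, 256, 1))
  depth <- as.integer(ihdr[9L]); ctype <- as.integer(ihdr[10L])
  interlace <- as.integer(ihdr[13L])
  if (depth != 8L) stop("only 8-bit PNGs are supported (got depth ", depth, ")")
  if (interlace != 0L) stop("interlaced PNGs are not supported")
  nch <- switch(as.character(ctype), "0" = 1L, "2" = 3L, "3" = 1L,
                "4" = 2L, "6" = 4L,
                stop("unsupported PNG color type ", ctype))
  scan <- memDecompress(do.call(c, idat), "gzip")
  stride <- 1L + nch * w
  if (length(scan) != h * stride) stop("PNG scanline data has wrong length")
  img <- matrix(0L, nrow = h, ncol = nch * w)
  prev <- integer(nch * w)
  for (j in seq_len(h)) {
    off <- (j - 1L) * stride
    filt <- as.integer(scan[off + 1L])
    cur <- as.integer(scan[off + 1L + seq_len(nch * w)])
    left <- function(v) c(integer(nch), v[seq_len(length(v) - nch)])
    cur <- switch(as.character(filt),
      "0" = cur,
      "1" = { out <- cur
              for (k in (nch + 1L):length(out))
                out[k] <- (out[k] + out[k - nch]) %% 256L
              out },
      "2" = (cur + prev) %% 256L,
      "3" = { out <- cur
              for (k in seq_along(out)) {
                a <- if (k > nch) out[k - nch] else 0L
                out[k] <- (out[k] + (a + prev[k]) %/% 2L) %% 256L
              }
              out },
      "4" = { out <- cur
              for (k in seq_along(out)) {
                a <- if (k > nch) out[k - nch] else 0L
                cc <- if (k > nch) prev[k - nch] else 0L
                out[k] <- (out[k] + paeth(a, prev[k], cc)) %% 256L
              }
              out },
      stop("unsupported PNG filter ", filt))
    img[j, ] <- cur
    prev <- cur
  }
  arr <- array(0, dim = c(h, w, 3L))
  if (ctype == 3L) {
    if (is.null(plte)) stop("palette PNG without PLTE chunk")
    pal <- matrix(as.integer(plte), ncol = 3L, byrow = TRUE)
    idx <- img[, seq_len(w), drop = FALSE] + 1L
    for (ch in 1:3) arr[, , ch] <- matrix(pal[idx, ch], h, w) / 255
  } else {
    take <- function(ch) img[, seq(ch, nch * w, by = nch), drop = FALSE] / 255
    if (nch >= 3L) for (ch in 1:3) arr[, , ch] <- take(ch)
    else for (ch in 1:3) arr[, , ch] <- take(1L)
  }
  arr
}
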
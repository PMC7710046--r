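# Minimal animated GIF89a writer. Frames are 8-bit palette indices sharing
# one global 256-colour table. Pixels are emitted as literal 9-bit LZW codes
# with a clear code every 254 pixels, which keeps the code table from
# growing -- a valid (if uncompressed) LZW stream that every decoder accepts.

u16le <- function(x) as.raw(c(x %% 256, x %/% 256))

gif_lzw_uncompressed <- function(indices) {
  # indices: integer vector in 0..255
  clear <- 256L; eoi <- 257L
  codes <- integer(0)
  n <- length(indices)
  block <- 254L
  starts <- seq(1L, n, by = block)
  pieces <- lapply(starts, function(s)
    c(clear, indices[s:min(s + block - 1L, n)]))
  codes <- c(unlist(pieces), eoi)
  # pack 9-bit codes LSB-first
  nbits <- length(codes) * 9L
  bits <- logical(nbits)
  for (k in seq_along(codes)) {
    v <- codes[k]
    bits[(k - 1L) * 9L + 1:9] <- bitwAnd(bitwShiftR(v, 0:8), 1L) == 1L
  }
  nbytes <- ceiling(nbits / 8)
  pad <- nbytes * 8L - nbits
  bits <- c(bits, logical(pad))
  bm <- matrix(bits, nrow = 8L)
  bytes <- as.raw(colSums(bm * 2L^(0:7)))
  bytes
}

gif_subblocks <- function(bytes) {
  n <- length(bytes)
  if (n == 0L) return(as.raw(0L))
  starts <- seq(1L, n, by = 255L)
  out <- lapply(starts, function(s) {
    chunk <- bytes[s:min(s + 254L, n)]
    c(as.raw(length(chunk)), chunk)
  })
  c(do.call(c, out), as.raw(0L))
}

#' Write an animated GIF from palette-indexed frames
#'
#' @param frames list of integer matrices (values 0-255, palette indices),
#'   all the same size; row 1 is the top row of the image.
#' @param palette matrix `256 x 3` of RGB values in `[0, 1]`, the shared
#'   global colour table.
#' @param file output path.
#' @param delay_cs frame delay in centiseconds (GIF time base).
#' @param loop number of animation loops, 0 = forever.
#' @return `file`, invisibly.
#' @export
write_gif <- function(frames, palette, file, delay_cs = 10L, loop = 0L) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            is.matrix(palette), nrow(palette) == 256L, ncol(palette) == 3L)
  h <- nrow(frames[[1L]]); w <- ncol(frames[[1L]])
  for (f in frames)
    if (nrow(f) != h || ncol(f) != w) stop("all GIF frames must share a size")
  pal_bytes <- as.raw(t(pmin(pmax(round(palette * 255), 0), 255)))
  out <- list(
    charToRaw("GIF89a"),
    u16le(w), u16le(h),
    as.raw(c(0xF7, 0x00, 0x00)),  # global table, 8 bits, 256 colours
    pal_bytes,
    # Netscape application extension: loop count
    as.raw(c(0x21, 0xFF, 0x0B)), charToRaw("NETSCAPE2.0"),
    as.raw(c(0x03, 0x01)), u16le(loop), as.raw(0x00))
  for (f in frames) {
    idx <- as.integer(t(f))  # row-major pixel order
    if (any(idx < 0L | idx > 255L)) stop("palette indices must be 0..255")
    out <- c(out, list(
      as.raw(c(0x21, 0xF9, 0x04, 0x04)), u16le(delay_cs),
      as.raw(c(0x00, 0x00)),                     # graphics control
      as.raw(0x2C), u16le(0L), u16le(0L), u16le(w), u16le(h),
      as.raw(0x00),                              # image descriptor
      as.raw(0x08),                              # LZW min code size
      gif_subblocks(gif_lzw_uncompressed(idx))))
  }
  out <- c(out, list(as.raw(0x3B)))
  writeBin(do.call(c, out), file)
  invisible(file)
}
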
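# AFM-style rendering of height maps: heights mapped linearly onto a colour
# palette between 0 and the map maximum (or a user-fixed z-range), +y up in
# the image.

#' Colour palette for AFM-style rendering
#'
#' `"afmhot"` is the classic AFM gold ramp (black through copper and orange
#' to white); `"gray"` is linear grayscale. Any palette name understood by
#' [grDevices::hcl.colors()] (e.g. `"Viridis"`) is also accepted.
#'
#' @param name palette name.
#' @param n number of colours.
#' @return character vector of `n` hex colours, dark (low) to bright (high).
#' @export
afm_palette <- function(name = "afmhot", n = 256L) {
  if (identical(name, "afmhot")) {
    grDevices::colorRampPalette(
      c("#000000", "#5A2800", "#A05000", "#E07800", "#FFA030",
        "#FFD080", "#FFFFFF"))(n)
  } else if (identical(name, "gray") || identical(name, "grey")) {
    grDevices::gray(seq(0, 1, length.out = n))
  } else {
    grDevices::hcl.colors(n, palette = name)
  }
}

heights_to_indices <- function(heights, zlim) {
  # linear map of heights onto palette indices 0..255
  span <- zlim[2L] - zlim[1L]
  if (span <= 0) return(matrix(0L, nrow(heights), ncol(heights)))
  t <- (heights - zlim[1L]) / span
  matrix(as.integer(pmin(pmax(round(t * 255), 0), 255)),
         nrow(heights), ncol(heights))
}

render_rgb <- function(heights, palette_rgb, zlim, upscale = 1L,
                       colorbar = FALSE) {
  idx <- heights_to_indices(heights, zlim)
  # +y up: map row 1 (smallest y) to the bottom of the image
  idx <- idx[rev(seq_len(nrow(idx))), , drop = FALSE]
  if (upscale > 1L) {
    idx <- idx[rep(seq_len(nrow(idx)), each = upscale),
               rep(seq_len(ncol(idx)), each = upscale), drop = FALSE]
  }
  if (colorbar) {
    h <- nrow(idx)
    bar <- matrix(rep(as.integer(round(seq(255, 0, length.out = h))),
                      times = 8L), h, 8L)
    gap <- matrix(0L, h, 2L)
    idx <- cbind(idx, gap, bar)
  }
  arr <- array(0, dim = c(nrow(idx), ncol(idx), 3L))
  for (ch in 1:3) arr[, , ch] <- matrix(palette_rgb[idx + 1L, ch],
                                        nrow(idx), ncol(idx))
  arr
}

palette_matrix <- function(colormap) {
  t(grDevices::col2rgb(afm_palette(colormap, 256L))) / 255
}

#' Render a height map to a PNG image
#'
#' Heights are mapped linearly onto the palette between `zlim[1]` and
#' `zlim[2]` (default 0 to the map maximum). The image is written with +y
#' up: the first grid row appears at the bottom. An optional colorbar strip
#' (dark = low, bright = high) is appended on the right.
#'
#' @param map an `afm_heightmap`.
#' @param file output PNG path.
#' @param colormap palette name, see [afm_palette()].
#' @param zlim numeric length-2 z-range (nm); `NULL` uses `c(0, max height)`.
#' @param upscale integer pixel-replication factor for viewing small grids.
#' @param colorbar append a palette strip on the right edge.
#' @return `file`, invisibly.
#' @export
render <- function(map, file, colormap = "afmhot", zlim = NULL,
                   upscale = 1L, colorbar = FALSE) {
  stopifnot(inherits(map, "afm_heightmap"))
  if (is.null(zlim)) zlim <- c(0, max(map$heights))
  stopifnot(length(zlim) == 2L)
  arr <- render_rgb(map$heights, palette_matrix(colormap), zlim,
                    upscale = as.integer(upscale), colorbar = colorbar)
  write_png(arr, file)
  invisible(file)
}
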
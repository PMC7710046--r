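# Post-processing of simulated maps and comparison against experimental AFM
# rasters: Gaussian blur, bilinear resampling, background cleaning, and the
# image correlation score.

#' Construct an AFM raster
#'
#' A grayscale image with a physical pixel size, the common currency for
#' comparing simulated and experimental AFM data. Simulated rasters carry
#' heights in nm; experimental ones arbitrary intensity units (the
#' correlation score is invariant under affine intensity rescaling, so no
#' height calibration is needed).
#'
#' @param pixels numeric `ny x nx` matrix (rows index y).
#' @param pixel_size physical pixel size, nm/pixel.
#' @param mask optional logical matrix of the same shape marking the region
#'   of interest; defaults to everything.
#' @return an `afm_raster`.
#' @export
afm_raster <- function(pixels, pixel_size, mask = NULL) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (any(!is.finite(pixels))) stop("raster pixels must be finite")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  stopifnot(is.logical(mask), all(dim(mask) == dim(pixels)))
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size),
                 mask = mask),
            class = "afm_raster")
}

#' @export
print.afm_raster <- function(x, ...) {
  cat(sprintf(
    "<afm_raster> %d x %d px, %.4g nm/px, intensity %.4g..%.4g, ROI %d px\n",
    ncol(x$pixels), nrow(x$pixels), x$pixel_size, min(x$pixels),
    max(x$pixels), sum(x$mask)))
  invisible(x)
}

#' Convert a height map to a raster
#'
#' @param map an `afm_heightmap`.
#' @return an `afm_raster` whose pixel values are the heights (nm) and whose
#'   pixel size is the grid step.
#' @export
as_raster <- function(map) {
  stopifnot(inherits(map, "afm_heightmap"))
  afm_raster(map$heights, map$grid$step)
}

# reflect (edge-repeating mirror) index mapping into 1..n
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  i <- ((i - 1L) %% p + p) %% p  # 0-based period 2n
  ifelse(i < n, i + 1L, p - i)
}

#' Gaussian blur of a raster
#'
#' Isotropic Gaussian convolution emulating the spatial averaging of
#' experimental AFM imaging. `sigma` is given in physical units (nm) and
#' converted to pixels through the raster's pixel size; the kernel is
#' truncated at 4 standard deviations and boundaries are handled by
#' reflection. `sigma = 0` is the identity.
#'
#' @param raster an `afm_raster`.
#' @param sigma Gaussian standard deviation, nm; must be `>= 0`.
#' @return the blurred `afm_raster` (mask unchanged).
#' @export
gaussian_blur <- function(raster, sigma) {
  stopifnot(inherits(raster, "afm_raster"))
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(raster)
  s <- sigma / raster$pixel_size
  r <- ceiling(4 * s)
  k <- exp(-(-r:r)^2 / (2 * s^2))
  k <- k / sum(k)
  P <- raster$pixels
  ny <- nrow(P); nx <- ncol(P)
  # separable convolution with reflected borders
  out <- matrix(0, ny, nx)
  for (o in -r:r)
    out <- out + k[o + r + 1L] * P[reflect_index(seq_len(ny) + o, ny), ,
                                   drop = FALSE]
  P2 <- matrix(0, ny, nx)
  for (o in -r:r)
    P2 <- P2 + k[o + r + 1L] * out[, reflect_index(seq_len(nx) + o, nx),
                                   drop = FALSE]
  raster$pixels <- P2
  raster
}

#' Bilinear resampling to a new pixel size
#'
#' Resamples the raster onto a grid with the requested pixel size spanning
#' the same physical area. Interpolation is bilinear between pixel centres,
#' with linear extrapolation at the borders so that affine intensity fields
#' (constants, ramps) are reproduced exactly. Used to co-register simulated
#' maps with experimental pixel grids before correlation scoring.
#'
#' @param raster an `afm_raster`.
#' @param new_pixel_size target pixel size, nm/pixel.
#' @return the resampled `afm_raster` (mask reset to full).
#' @export
resample <- function(raster, new_pixel_size) {
  stopifnot(inherits(raster, "afm_raster"))
  if (!is.numeric(new_pixel_size) || new_pixel_size <= 0)
    stop("new_pixel_size must be positive")
  P <- raster$pixels
  ny <- nrow(P); nx <- ncol(P); ps <- raster$pixel_size
  nx2 <- as.integer(round(nx * ps / new_pixel_size))
  ny2 <- as.integer(round(ny * ps / new_pixel_size))
  if (nx2 < 2L || ny2 < 2L)
    stop("target pixel size leaves fewer than 2 pixels per axis")
  # fractional source index of each target pixel centre
  tx <- ((seq_len(nx2) - 0.5) * new_pixel_size) / ps + 0.5
  ty <- ((seq_len(ny2) - 0.5) * new_pixel_size) / ps + 0.5
  ix <- pmin(pmax(floor(tx), 1L), nx - 1L); fx <- tx - ix
  iy <- pmin(pmax(floor(ty), 1L), ny - 1L); fy <- ty - iy
  # separable: interpolate columns then rows
  A <- P[iy, , drop = FALSE] * (1 - fy) + P[iy + 1L, , drop = FALSE] * fy
  out <- A[, ix, drop = FALSE] * rep(1 - fx, each = ny2) +
    A[, ix + 1L, drop = FALSE] * rep(fx, each = ny2)
  afm_raster(out, new_pixel_size)
}

#' Background cleaning by intensity threshold
#'
#' Pixels strictly below `threshold * max(pixels)` are zeroed and removed
#' from the region-of-interest mask; all other pixels are untouched. This is
#' the simple stand-in for manual background removal when preparing images
#' for correlation. Idempotent at a fixed threshold.
#'
#' @param raster an `afm_raster`.
#' @param threshold fraction of the maximum intensity, in `[0, 1)`.
#' @return the cleaned `afm_raster`.
#' @export
clean_background <- function(raster, threshold) {
  stopifnot(inherits(raster, "afm_raster"))
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1)
    stop("threshold must lie in [0, 1)")
  if (threshold == 0) return(raster)
  cut <- threshold * max(raster$pixels)
  below <- raster$pixels < cut
  raster$pixels[below] <- 0
  raster$mask <- raster$mask & !below
  raster
}

#' Image correlation score between two rasters
#'
#' Pearson correlation coefficient of pixel intensities over the joint
#' region of interest (intersection of both masks). The score is invariant
#' under affine intensity rescaling of either image, which absorbs the
#' unknown height calibration of experimental AFM data. A cosine-similarity
#' variant (no mean centring) is available as an alternative.
#'
#' @param sim,exp `afm_raster` objects of identical shape (resample first if
#'   needed).
#' @param method `"pearson"` (default) or `"cosine"`.
#' @return the correlation score C in `[-1, 1]`.
#' @export
correlation <- function(sim, exp, method = c("pearson", "cosine")) {
  method <- match.arg(method)
  stopifnot(inherits(sim, "afm_raster"), inherits(exp, "afm_raster"))
  if (!all(dim(sim$pixels) == dim(exp$pixels)))
    stop("rasters must have identical shapes; resample() first")
  roi <- sim$mask & exp$mask
  if (sum(roi) < 3L) stop("joint region of interest has fewer than 3 pixels")
  a <- sim$pixels[roi]; b <- exp$pixels[roi]
  if (method == "pearson") {
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("undefined correlation: zero intensity variance inside the ROI")
    stats::cor(a, b)
  } else {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0)
      stop("undefined cosine similarity: all-zero intensities inside the ROI")
    sum(a * b) / (na * nb)
  }
}

#' Read a raster from disk
#'
#' Accepts either the package's plain-text matrix format (written by
#' [write_heightmap()]) or an 8-bit PNG. PNGs are converted to grayscale by
#' Rec. 709 luminance (0.2126 R + 0.7152 G + 0.0722 B); text matrices keep
#' their values (nm for simulated maps).
#'
#' @param file path to a text matrix or PNG file.
#' @param pixel_size physical pixel size in nm/pixel; required for PNG input,
#'   ignored for text input (the header carries the step).
#' @return an `afm_raster`.
#' @export
read_raster <- function(file, pixel_size = NULL) {
  magic <- readBin(file, "raw", 8L)
  if (length(magic) == 8L &&
      identical(magic, charToRaw("\x89PNG\r\n\x1a\n"))) {
    if (is.null(pixel_size))
      stop("pixel_size is required when reading a PNG raster")
    arr <- read_png(file)
    g <- 0.2126 * arr[, , 1L] + 0.7152 * arr[, , 2L] + 0.0722 * arr[, , 3L]
    # image row 1 is the top (largest y); flip to map row order (y ascending)
    afm_raster(g[rev(seq_len(nrow(g))), , drop = FALSE], pixel_size)
  } else {
    as_raster(read_heightmap(file))
  }
}

#' Restrict the region of interest of a raster
#'
#' @param raster an `afm_raster`.
#' @param rect integer vector `c(i0, j0, i1, j1)` in pixel coordinates
#'   (column, row, inclusive), or `NULL`.
#' @param mask_file optional path to a same-shape 0/1 text matrix.
#' @return the raster with its mask intersected with the requested ROI.
#' @export
set_roi <- function(raster, rect = NULL, mask_file = NULL) {
  stopifnot(inherits(raster, "afm_raster"))
  m <- raster$mask
  if (!is.null(rect)) {
    stopifnot(length(rect) == 4L)
    sel <- matrix(FALSE, nrow(m), ncol(m))
    sel[rect[2L]:rect[4L], rect[1L]:rect[3L]] <- TRUE
    m <- m & sel
  }
  if (!is.null(mask_file)) {
    mm <- as.matrix(utils::read.table(mask_file))
    if (!all(dim(mm) == dim(m))) stop("ROI mask shape does not match raster")
    m <- m & (mm != 0)
  }
  raster$mask <- m
  raster
}
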
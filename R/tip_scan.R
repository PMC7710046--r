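# The simulated-scanning engine. The tip is a rigid probe sphere of radius R
# capped by a tangent infinite cone of half-angle alpha (axis vertical); the
# image is formed by hard, non-elastic collisions of this tip with the van
# der Waals spheres of the staged structure. No elastic deformation and no
# experimental noise are modelled.

#' Construct a tip model
#'
#' @param R probe sphere radius, nm.
#' @param alpha_deg cone half-angle in degrees, measured from the vertical
#'   axis; must lie strictly between 0 and 90.
#' @return an `afm_tip`: list with `R` (nm) and `alpha` (radians).
#' @examples
#' afm_tip(R = 1.0, alpha_deg = 10)
#' @export
afm_tip <- function(R = 1.0, alpha_deg = 10) {
  if (!is.numeric(R) || R <= 0) stop("probe sphere radius R must be positive")
  if (!is.numeric(alpha_deg) || alpha_deg <= 0 || alpha_deg >= 90)
    stop("cone half-angle must be strictly between 0 and 90 degrees")
  structure(list(R = as.numeric(R), alpha = alpha_deg * pi / 180),
            class = "afm_tip")
}

#' @export
print.afm_tip <- function(x, ...) {
  cat(sprintf("<afm_tip> R = %.4g nm, alpha = %.4g deg\n",
              x$R, x$alpha * 180 / pi))
  invisible(x)
}

#' Closed-form tip--atom collision height
#'
#' Height of the lowest point of the tip at the moment it first touches a van
#' der Waals sphere of radius `atom_r` centred at height `atom_z`, when the
#' tip axis passes at lateral distance `d` from the atom centre. Two contact
#' regimes exist and meet continuously at `d = (R + atom_r) * cos(alpha)`:
#'
#' * probe-sphere contact (small `d`):
#'   `h = atom_z - R + sqrt((R + atom_r)^2 - d^2)`
#' * cone-flank contact (large `d`):
#'   `h = atom_z - R + (R + atom_r) / sin(alpha) - d / tan(alpha)`
#'
#' The cone is treated as infinite, so every atom returns a finite (possibly
#' negative) height; [scan()] clamps at the stage plane.
#'
#' @param tip an [afm_tip()].
#' @param atom_z atom centre height, nm (vectorized).
#' @param atom_r atom van der Waals radius, nm (vectorized).
#' @param d lateral distance from the tip axis to the atom centre, nm,
#'   `>= 0` (vectorized).
#' @return collision height(s), nm, in the same z frame as `atom_z`.
#' @examples
#' tip <- afm_tip(R = 1, alpha_deg = 15)
#' collision_height(tip, atom_z = 0.15, atom_r = 0.15, d = 0)    # 0.30
#' collision_height(tip, atom_z = 0.15, atom_r = 0.15, d = 0.5)  # ~0.1856
#' @export
collision_height <- function(tip, atom_z, atom_r, d) {
  stopifnot(inherits(tip, "afm_tip"))
  if (any(atom_r <= 0)) stop("atom radius must be positive")
  if (any(d < 0)) stop("lateral distance must be non-negative")
  rr <- tip$R + atom_r
  dcrit <- rr * cos(tip$alpha)
  sphere <- d <= dcrit
  h <- numeric(length(d))
  if (any(sphere)) {
    h[sphere] <- (atom_z - tip$R + sqrt(rr^2 - d^2))[sphere]
  }
  if (any(!sphere)) {
    h[!sphere] <- (atom_z - tip$R + rr / sin(tip$alpha) -
                     d / tan(tip$alpha))[!sphere]
  }
  h
}

#' Simulated AFM scan of a staged structure
#'
#' For each cell of the scanning grid, the tip is lowered along the vertical
#' axis through the cell centre until it first touches any van der Waals
#' sphere; the cell records the height of the tip's lowest point above the
#' stage, clamped at 0 (the tip cannot penetrate the stage). The result is
#' the simulated AFM image before any rendering or post-processing.
#'
#' @param structure an `afm_structure`, already passed through [stage()].
#' @param tip an [afm_tip()].
#' @param grid an `afm_grid`; defaults to [build_grid()] of the structure at
#'   `step`/`margin`.
#' @param step,margin grid parameters used when `grid` is NULL, nm.
#' @return an `afm_heightmap`: list with `grid` and a `ny x nx` matrix
#'   `heights` (rows index y, columns index x), stage-relative nm.
#' @export
scan <- function(structure, tip = afm_tip(), grid = NULL,
                 step = 0.5, margin = 2) {
  stopifnot(inherits(structure, "afm_structure"), inherits(tip, "afm_tip"))
  if (is.null(grid)) grid <- build_grid(structure, step = step,
                                        margin = margin)
  stopifnot(inherits(grid, "afm_grid"))
  a <- structure$atoms
  xs <- grid_x(grid)
  ys <- grid_y(grid)
  H <- matrix(0, nrow = grid$ny, ncol = grid$nx)
  sin_a <- sin(tip$alpha)
  cot_a <- cos(tip$alpha) / sin_a
  for (i in seq_len(nrow(a))) {
    rr <- tip$R + a$radius[i]
    d2 <- outer((ys - a$y[i])^2, (xs - a$x[i])^2, `+`)
    d <- sqrt(d2)
    hi <- ifelse(d <= rr * cos(tip$alpha),
                 a$z[i] - tip$R + sqrt(pmax(rr^2 - d2, 0)),
                 a$z[i] - tip$R + rr / sin_a - d * cot_a)
    H <- pmax(H, hi)
  }
  afm_heightmap(grid, H)
}

#' Construct a height map object
#'
#' @param grid an `afm_grid`.
#' @param heights numeric `ny x nx` matrix of stage-relative heights, nm.
#' @return an `afm_heightmap`.
#' @export
afm_heightmap <- function(grid, heights) {
  stopifnot(inherits(grid, "afm_grid"), is.matrix(heights))
  if (nrow(heights) != grid$ny || ncol(heights) != grid$nx)
    stop("heights matrix must be ny x nx")
  if (any(!is.finite(heights))) stop("heights must be finite")
  if (any(heights < 0)) stop("heights must be >= 0 (stage-relative)")
  structure(list(grid = grid, heights = heights), class = "afm_heightmap")
}

#' @export
print.afm_heightmap <- function(x, ...) {
  cat(sprintf(
    "<afm_heightmap> %d x %d cells, step %.4g nm, max height %.4g nm\n",
    x$grid$nx, x$grid$ny, x$grid$step, max(x$heights)))
  invisible(x)
}

#' Write a height map as a plain-text matrix
#'
#' Tab-separated values, one line per grid row (row 1 is the smallest y),
#' preceded by `#`-prefixed header lines carrying the grid geometry and any
#' extra metadata (tip parameters, run configuration). Values are printed
#' with 17 significant digits so that [read_heightmap()] restores them
#' bit-exactly.
#'
#' @param map an `afm_heightmap`.
#' @param file output path.
#' @param meta optional named character/numeric vector of extra
#'   `# key = value` header lines.
#' @return `file`, invisibly.
#' @export
write_heightmap <- function(map, file, meta = NULL) {
  stopifnot(inherits(map, "afm_heightmap"))
  g <- map$grid
  hdr <- c("# afmscan heightmap v1",
           sprintf("# nx = %d", g$nx),
           sprintf("# ny = %d", g$ny),
           sprintf("# step_nm = %.17g", g$step),
           sprintf("# x0_nm = %.17g", g$x0),
           sprintf("# y0_nm = %.17g", g$y0))
  if (!is.null(meta))
    hdr <- c(hdr, sprintf("# %s = %s", names(meta), as.character(meta)))
  rows <- apply(map$heights, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(hdr, rows), file)
  invisible(file)
}

#' Read a height map written by [write_heightmap()]
#'
#' @param file path to the text matrix.
#' @return an `afm_heightmap`; extra header metadata is attached as the
#'   `"meta"` attribute (named character vector).
#' @export
read_heightmap <- function(file) {
  lines <- readLines(file, warn = FALSE)
  is_hdr <- startsWith(lines, "#")
  hdr <- sub("^#\\s*", "", lines[is_hdr])
  kv <- regmatches(hdr, regexec("^([^=]+?)\\s*=\\s*(.*)$", hdr))
  kv <- kv[lengths(kv) == 3L]
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  names(vals) <- trimws(keys)
  need <- c("nx", "ny", "step_nm", "x0_nm", "y0_nm")
  if (!all(need %in% names(vals)))
    stop("missing heightmap header field(s): ",
         paste(setdiff(need, names(vals)), collapse = ", "))
  body <- lines[!is_hdr & nzchar(trimws(lines))]
  H <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE), as.numeric))
  g <- afm_grid(as.numeric(vals[["x0_nm"]]), as.numeric(vals[["y0_nm"]]),
                as.numeric(vals[["step_nm"]]),
                as.integer(vals[["nx"]]), as.integer(vals[["ny"]]))
  map <- afm_heightmap(g, H)
  attr(map, "meta") <- vals[setdiff(names(vals), need)]
  map
}
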
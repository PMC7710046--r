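# Rigid-body orientation, staging on the virtual surface, and the scanning
# grid. Heights everywhere are measured from the stage plane z = 0 with the
# tip approaching from +z.

#' Rotation matrix from intrinsic Z-Y-Z Euler angles
#'
#' Angles are in degrees, applied intrinsically in the order z, then y', then
#' z'' (so the composed matrix is `Rz(phi) %*% Ry(theta) %*% Rz(psi)`).
#'
#' @param phi,theta,psi Euler angles, degrees.
#' @return a 3x3 proper rotation matrix.
#' @examples
#' euler_zyz(90, 0, 0) %*% c(1, 0, 0)  # -> (0, 1, 0)
#' @export
euler_zyz <- function(phi = 0, theta = 0, psi = 0) {
  d2r <- pi / 180
  rz <- function(a) matrix(c(cos(a), sin(a), 0,
                             -sin(a), cos(a), 0,
                             0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a),
                             0, 1, 0,
                             sin(a), 0, cos(a)), 3, 3)
  rz(phi * d2r) %*% ry(theta * d2r) %*% rz(psi * d2r)
}

check_rotation <- function(rot, tol = 1e-9) {
  if (!is.matrix(rot) || !all(dim(rot) == c(3L, 3L)) || !is.numeric(rot))
    stop("rotation must be a numeric 3x3 matrix")
  if (max(abs(crossprod(rot) - diag(3))) > tol)
    stop("rotation matrix is not orthonormal (tolerance 1e-9)")
  if (abs(det(rot) - 1) > tol)
    stop("rotation matrix must be proper (determinant +1)")
  invisible(rot)
}

#' Rotate a structure about its centroid
#'
#' Every atom position `p` is replaced by `rot %*% (p - centroid) + centroid`,
#' where the centroid is the unweighted mean of atom centres. Radii and atom
#' order are untouched. This is the headless equivalent of re-orienting the
#' molecule in a viewer before scanning.
#'
#' @param structure an `afm_structure`.
#' @param rot a proper 3x3 rotation matrix, e.g. from [euler_zyz()].
#' @return the rotated `afm_structure`.
#' @export
orient <- function(structure, rot = diag(3)) {
  stopifnot(inherits(structure, "afm_structure"))
  check_rotation(rot)
  a <- structure$atoms
  p <- cbind(a$x, a$y, a$z)
  ctr <- colMeans(p)
  q <- sweep(sweep(p, 2L, ctr) %*% t(rot), 2L, ctr, `+`)
  structure$atoms$x <- q[, 1L]
  structure$atoms$y <- q[, 2L]
  structure$atoms$z <- q[, 3L]
  structure
}

#' Rest a structure on the virtual surface
#'
#' Translates the structure along z so that the lowest point of any van der
#' Waals sphere touches the stage plane: after staging,
#' `min(z_i - r_i) == 0` exactly. The returned offset records the applied
#' translation so that trajectory frames can share one reference frame.
#'
#' @param structure an `afm_structure`.
#' @param offset optional explicit z-translation (nm) to apply instead of
#'   computing one; used to stage trajectory frames consistently.
#' @return the staged `afm_structure`, with attribute `"stage_offset"` giving
#'   the translation that was applied.
#' @export
stage <- function(structure, offset = NULL) {
  stopifnot(inherits(structure, "afm_structure"))
  a <- structure$atoms
  if (is.null(offset)) offset <- -min(a$z - a$radius)
  structure$atoms$z <- a$z + offset
  attr(structure, "stage_offset") <- offset
  structure
}

#' Construct a scanning grid
#'
#' Builds the lateral grid of tip positions. The grid spans the van der
#' Waals bounding box of the structure plus a margin on each side; cell
#' centres sit at `origin + (i, j) * step`. The origin is snapped so that one
#' cell centre lies exactly at the lateral position of the structure
#' centroid, which makes maps reproducible under small bounding-box changes
#' and makes coarse grids subsample fine ones built around the same centroid.
#'
#' @param structure a (typically staged) `afm_structure`; alternatively pass
#'   `xlim`/`ylim` explicitly and omit the structure.
#' @param step scanning step size a, nm.
#' @param margin extra span on every side, nm (default 2 nm so cone-flank
#'   contacts near the boundary are captured at typical tip geometries).
#' @param xlim,ylim optional explicit spans overriding the structure bounds.
#' @param center optional lateral snap point `(x, y)`; defaults to the
#'   structure centroid.
#' @return an `afm_grid`: list with `x0`, `y0`, `step`, `nx`, `ny`.
#' @export
build_grid <- function(structure = NULL, step = 0.5, margin = 2,
                       xlim = NULL, ylim = NULL, center = NULL) {
  if (!is.numeric(step) || step <= 0) stop("grid step must be positive")
  if (margin < 0) stop("margin must be non-negative")
  if (is.null(xlim) || is.null(ylim)) {
    stopifnot(inherits(structure, "afm_structure"))
    a <- structure$atoms
    xlim <- c(min(a$x - a$radius) - margin, max(a$x + a$radius) + margin)
    ylim <- c(min(a$y - a$radius) - margin, max(a$y + a$radius) + margin)
    if (is.null(center)) center <- c(mean(a$x), mean(a$y))
  }
  if (is.null(center)) center <- c(mean(xlim), mean(ylim))
  x0 <- center[1L] - step * ceiling((center[1L] - xlim[1L]) / step)
  y0 <- center[2L] - step * ceiling((center[2L] - ylim[1L]) / step)
  nx <- floor((xlim[2L] - x0) / step) + 1L
  ny <- floor((ylim[2L] - y0) / step) + 1L
  afm_grid(x0, y0, step, nx, ny)
}

#' Construct a scanning grid from explicit geometry
#'
#' @param x0,y0 lateral position of the first cell centre, nm.
#' @param step cell spacing, nm.
#' @param nx,ny cell counts along x and y.
#' @return an `afm_grid` object.
#' @export
afm_grid <- function(x0, y0, step, nx, ny) {
  if (step <= 0) stop("grid step must be positive")
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 1L || ny < 1L) stop("grid must have at least one cell per axis")
  structure(list(x0 = as.numeric(x0), y0 = as.numeric(y0),
                 step = as.numeric(step), nx = nx, ny = ny),
            class = "afm_grid")
}

#' @export
print.afm_grid <- function(x, ...) {
  cat(sprintf(
    "<afm_grid> %d x %d cells, step %.4g nm, origin (%.4g, %.4g) nm\n",
    x$nx, x$ny, x$step, x$x0, x$y0))
  invisible(x)
}

grid_x <- function(grid) grid$x0 + (seq_len(grid$nx) - 1L) * grid$step
grid_y <- function(grid) grid$y0 + (seq_len(grid$ny) - 1L) * grid$step

#' Lateral coordinates of the grid cell centres
#'
#' @param grid an `afm_grid`.
#' @return list with numeric vectors `x` (length `nx`) and `y` (length `ny`),
#'   nm.
#' @export
grid_centers <- function(grid) {
  stopifnot(inherits(grid, "afm_grid"))
  list(x = grid_x(grid), y = grid_y(grid))
}
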
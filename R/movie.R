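# Frame-by-frame simulated scanning of trajectories and movie export.

#' Scan every frame of a trajectory on a shared grid
#'
#' All frames are rotated with the same orientation, staged with one common
#' z-offset (computed from the first frame, so genuine vertical motion
#' between frames stays visible instead of being normalised away), and
#' scanned on one grid built from the union of all frames' bounding boxes
#' (so domains moving between frames stay in-frame). Per-frame restaging is
#' available behind `restage_per_frame` for workflows that want every frame
#' resting on the surface independently.
#'
#' @param traj an `afm_trajectory` (or a single `afm_structure`, treated as
#'   a 1-frame trajectory).
#' @param rot 3x3 rotation matrix applied to every frame, see [euler_zyz()].
#' @param tip an [afm_tip()].
#' @param step,margin scanning grid parameters, nm.
#' @param restage_per_frame recompute the stage offset for every frame
#'   instead of reusing frame 1's offset.
#' @return an `afm_movie`: list with `maps` (list of `afm_heightmap` on the
#'   identical grid), `grid`, and `labels`.
#' @export
scan_trajectory <- function(traj, rot = diag(3), tip = afm_tip(),
                            step = 0.5, margin = 2,
                            restage_per_frame = FALSE) {
  if (inherits(traj, "afm_structure")) traj <- afm_trajectory(list(traj))
  stopifnot(inherits(traj, "afm_trajectory"))
  oriented <- lapply(traj$frames, orient, rot = rot)
  first <- stage(oriented[[1L]])
  off <- attr(first, "stage_offset")
  staged <- c(list(first),
              lapply(oriented[-1L], function(s)
                if (restage_per_frame) stage(s) else stage(s, offset = off)))
  # union bounding box over all staged frames
  lims <- sapply(staged, function(s) {
    a <- s$atoms
    c(min(a$x - a$radius), max(a$x + a$radius),
      min(a$y - a$radius), max(a$y + a$radius))
  })
  ctr <- colMeans(first$atoms[, c("x", "y")])
  grid <- build_grid(step = step,
                     xlim = c(min(lims[1L, ]) - margin,
                              max(lims[2L, ]) + margin),
                     ylim = c(min(lims[3L, ]) - margin,
                              max(lims[4L, ]) + margin),
                     center = as.numeric(ctr))
  maps <- lapply(staged, function(s) {
    # vertical motion can carry spheres below the common stage; the scanner
    # clamps at z = 0, matching a tip that cannot probe below the surface
    scan(s, tip = tip, grid = grid)
  })
  structure(list(maps = maps, grid = grid,
                 labels = vapply(staged, function(s) s$label, character(1))),
            class = "afm_movie")
}

#' @export
print.afm_movie <- function(x, ...) {
  cat(sprintf("<afm_movie> %d frame(s) on a %d x %d grid (step %.4g nm)\n",
              length(x$maps), x$grid$nx, x$grid$ny, x$grid$step))
  invisible(x)
}

#' Export a scanned trajectory as a PNG sequence plus an animated GIF
#'
#' All frames share one z-colour scale fixed at the global maximum height, so
#' relative protrusion changes between frames are directly comparable.
#' Frame PNGs are written as `<prefix>_NNNN.png` (zero-padded index) and the
#' animation as `<prefix>.gif`.
#'
#' @param movie an `afm_movie` from [scan_trajectory()].
#' @param prefix output path prefix.
#' @param colormap palette name, see [afm_palette()].
#' @param fps frames per second of the GIF.
#' @param upscale integer pixel-replication factor.
#' @param zlim optional fixed z-range (nm); default `c(0, global max)`.
#' @return named list with `png` (paths) and `gif` (path), invisibly.
#' @export
export_movie <- function(movie, prefix, colormap = "afmhot", fps = 5,
                         upscale = 1L, zlim = NULL) {
  stopifnot(inherits(movie, "afm_movie"), length(movie$maps) >= 1L)
  if (is.null(zlim))
    zlim <- c(0, max(vapply(movie$maps, function(m) max(m$heights),
                            numeric(1))))
  pal <- palette_matrix(colormap)
  pngs <- character(length(movie$maps))
  gif_frames <- vector("list", length(movie$maps))
  up <- as.integer(upscale)
  for (k in seq_along(movie$maps)) {
    H <- movie$maps[[k]]$heights
    pngs[k] <- sprintf("%s_%04d.png", prefix, k)
    write_png(render_rgb(H, pal, zlim, upscale = up), pngs[k])
    idx <- heights_to_indices(H, zlim)
    idx <- idx[rev(seq_len(nrow(idx))), , drop = FALSE]
    if (up > 1L)
      idx <- idx[rep(seq_len(nrow(idx)), each = up),
                 rep(seq_len(ncol(idx)), each = up), drop = FALSE]
    gif_frames[[k]] <- idx
  }
  gif <- paste0(prefix, ".gif")
  write_gif(gif_frames, pal, gif, delay_cs = max(1L, round(100 / fps)))
  invisible(list(png = pngs, gif = gif))
}
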
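# Brute-force tip-lowering oracle, independent of the closed-form collision
# algebra. The tip boundary is treated as a graph z = h + f(rho) over the
# lateral plane, where f is the profile of a probe sphere (radius R) capped
# by its tangent cone (half-angle alpha), measured from the tip's lowest
# point. The tip is lowered until its surface first meets the atom sphere;
# the contact height is found by discretizing the lateral coordinate at
# resolution dx and maximizing the clearance condition directly.

oracle_tip_profile <- function(rho, R, alpha) {
  f <- R - R / sin(alpha) + rho / tan(alpha)   # cone flank
  on_sphere <- rho <= R * cos(alpha)
  f[on_sphere] <- R - sqrt(R^2 - rho[on_sphere]^2)
  f
}

# collision height of the tip over one atom, axis at lateral distance d
oracle_collision <- function(R, alpha, atom_z, atom_r, d, dx = 1e-4) {
  u <- seq(-atom_r, atom_r, by = dx)
  s <- sqrt(pmax(atom_r^2 - u^2, 0))     # sphere upper envelope
  f <- oracle_tip_profile(abs(d + u), R, alpha)
  max(atom_z + s - f)
}

# full-map oracle: per cell, lower the tip over all atoms; clamp at stage
oracle_scan <- function(structure, tip, grid, dx = 1e-4) {
  a <- structure$atoms
  xs <- grid$x0 + (seq_len(grid$nx) - 1L) * grid$step
  ys <- grid$y0 + (seq_len(grid$ny) - 1L) * grid$step
  cx <- rep(xs, each = grid$ny)
  cy <- rep(ys, times = grid$nx)
  H <- rep(0, grid$nx * grid$ny)
  for (i in seq_len(nrow(a))) {
    u <- seq(-a$radius[i], a$radius[i], by = dx)
    s <- sqrt(pmax(a$radius[i]^2 - u^2, 0))
    d <- sqrt((cx - a$x[i])^2 + (cy - a$y[i])^2)
    # rho for every (sample, cell) pair; columns are cells
    rho <- abs(outer(u, d, `+`))
    dim(rho) <- NULL
    f <- oracle_tip_profile(rho, tip$R, tip$alpha)
    M <- (s - f)                     # s recycles down each cell's column
    dim(M) <- c(length(u), length(d))
    hi <- a$z[i] + apply(M, 2L, max)
    H <- pmax(H, hi)
  }
  matrix(H, nrow = grid$ny, ncol = grid$nx)
}

# random staged structure in a cubic box, for oracle comparisons
random_staged <- function(n = 10L, box = 2, seed = 1L,
                          elements = c("C", "N", "O", "S")) {
  stage(make_fixture("random", n = n, box = box, seed = seed,
                     elements = elements)$frames[[1L]])
}
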
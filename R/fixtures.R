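# Synthetic-structure generator. Produces valid in-memory structures (and,
# through write_fixture_pdb, valid PDB files) with exactly known geometry so
# that every pipeline stage can be tested without downloading real data.
# Real element symbols are used so the radius table is exercised; oversized
# pseudo-domain spheres are available through a radius override.

#' Generate a synthetic test structure or trajectory
#'
#' Deterministic for a given parameter set and seed (the seed only matters
#' for `kind = "random"`). Available kinds:
#'
#' * `single_atom` — one atom at the origin.
#' * `dimer` — two atoms `spacing` nm apart along x.
#' * `chain` — `n` atoms in a straight line along x, `spacing` nm apart.
#' * `helix` — `n` atoms on the parametric helix
#'   `(r cos(k w), r sin(k w), k p / n_turn)` with radius `helix_radius`,
#'   pitch `pitch` (rise per full turn) and `per_turn` atoms per turn.
#' * `ring` — `n` atoms equally spaced on a circle of radius `ring_radius`
#'   in the x-y plane; a coarse mock of ring-shaped oligomers such as a
#'   7-mer chaperone ring. With `frames > 1` an "opening" trajectory is
#'   produced: each subunit pivots outward about its base position by a tilt
#'   angle interpolated linearly from 0 to `tilt_max_deg` across frames,
#'   which widens the central cavity frame by frame.
#' * `random` — `n` atoms uniform in a cube of edge `box` centred at the
#'   origin, elements drawn from `elements`.
#'
#' @param kind fixture kind, see above.
#' @param n atom count (chain, helix, ring, random).
#' @param element element symbol used for regular fixtures.
#' @param elements candidate symbols for `random`.
#' @param spacing inter-atom spacing, nm.
#' @param ring_radius circle radius, nm.
#' @param helix_radius,pitch,per_turn helix parameters (nm, nm/turn, atoms).
#' @param subunit_length pivot-to-centre distance of ring subunits, nm.
#' @param frames number of trajectory frames (ring opening); 1 = static.
#' @param tilt_max_deg final outward tilt of ring subunits, degrees.
#' @param box edge length of the random cube, nm.
#' @param seed integer seed for `random`.
#' @param radius optional per-atom radius override, nm (pseudo-domains).
#' @return an `afm_trajectory` (1 frame unless `frames > 1`).
#' @export
make_fixture <- function(kind = c("single_atom", "dimer", "chain", "helix",
                                  "ring", "random"),
                         n = 7L, element = "C",
                         elements = c("C", "N", "O", "S"),
                         spacing = 0.4, ring_radius = 2,
                         helix_radius = 0.5, pitch = 0.55, per_turn = 10L,
                         subunit_length = 1, frames = 1L, tilt_max_deg = 35,
                         box = 2, seed = 1L, radius = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 1L, spacing > 0, ring_radius > 0, helix_radius > 0,
            pitch > 0, frames >= 1L, box > 0, subunit_length > 0)
  mk <- function(el, x, y, z, lab) {
    r <- if (is.null(radius)) element_radius(el) else rep(radius,
                                                          length(el))
    afm_structure(el, x, y, z, radius = r, label = lab)
  }
  lab <- sprintf("fixture kind=%s n=%d seed=%d", kind, n, as.integer(seed))
  frames_out <- switch(kind,
    single_atom = list(mk(element, 0, 0, 0, lab)),
    dimer = list(mk(rep(element, 2L), c(0, spacing), c(0, 0), c(0, 0), lab)),
    chain = list(mk(rep(element, n), (seq_len(n) - 1L) * spacing,
                    numeric(n), numeric(n), lab)),
    helix = {
      k <- seq_len(n) - 1L
      w <- 2 * pi / per_turn
      list(mk(rep(element, n), helix_radius * cos(k * w),
              helix_radius * sin(k * w), k * pitch / per_turn, lab))
    },
    ring = {
      phi <- 2 * pi * (seq_len(n) - 1L) / n
      radial <- cbind(cos(phi), sin(phi))
      pivot <- ring_radius * radial
      tilts <- if (frames == 1L) 0
               else seq(0, tilt_max_deg, length.out = frames) * pi / 180
      lapply(seq_along(tilts), function(f) {
        tau <- tilts[f]
        ctr <- pivot + subunit_length * sin(tau) * radial
        mk(rep(element, n), ctr[, 1L], ctr[, 2L],
           rep(subunit_length * cos(tau), n),
           sprintf("%s frame=%d tilt=%.2fdeg", lab, f, tau * 180 / pi))
      })
    },
    random = {
      set.seed(as.integer(seed))
      el <- sample(elements, n, replace = TRUE)
      list(mk(el, stats::runif(n, -box / 2, box / 2),
              stats::runif(n, -box / 2, box / 2),
              stats::runif(n, -box / 2, box / 2), lab))
    })
  afm_trajectory(frames_out)
}
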
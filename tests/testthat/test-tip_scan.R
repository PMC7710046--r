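test_that("collision_height: apex contact, oracle value, domain checks", {
  tip <- afm_tip(R = 1.0, alpha_deg = 15)
  # d = 0 gives apex contact at atom_z + atom_r for any tip
  for (R in c(0.5, 1, 1.5)) for (al in c(5, 10, 15)) {
    t2 <- afm_tip(R, al)
    expect_equal(collision_height(t2, atom_z = 0.4, atom_r = 0.15, d = 0),
                 0.55, tolerance = 1e-12)
  }
  # frozen value computed with the brute-force tip-lowering oracle
  h <- collision_height(tip, atom_z = 0.15, atom_r = 0.15, d = 0.5)
  expect_equal(h, oracle_collision(1.0, 15 * pi / 180, 0.15, 0.15, 0.5),
               tolerance = 1e-3)
  expect_equal(h, 0.1856, tolerance = 1e-3)
  expect_error(collision_height(tip, 0, -0.1, 0), "radius")
  expect_error(collision_height(tip, 0, 0.1, -1), "distance")
  expect_error(afm_tip(R = -1), "positive")
  expect_error(afm_tip(alpha_deg = 95), "between 0 and 90")
})

test_that("sphere and cone branches agree at the tangency distance", {
  set.seed(42)
  n <- 1000L
  R <- stats::runif(n, 0.2, 2)
  r <- stats::runif(n, 0.05, 0.3)
  al <- stats::runif(n, 2, 60) * pi / 180
  d <- (R + r) * cos(al)
  h_sphere <- -R + sqrt((R + r)^2 - d^2)
  h_cone <- -R + (R + r) / sin(al) - d / tan(al)
  expect_lt(max(abs(h_sphere - h_cone)), 1e-12)
  # and the implementation is continuous across the branch point
  for (k in sample(n, 20L)) {
    t2 <- afm_tip(R[k], al[k] * 180 / pi)
    lo <- collision_height(t2, 0, r[k], d[k] * (1 - 1e-12))
    hi <- collision_height(t2, 0, r[k], d[k] * (1 + 1e-12))
    expect_lt(abs(lo - hi), 1e-10)
  }
})

test_that("single-atom map peaks at twice the VdW radius", {
  for (el in c("C", "O", "H")) {
    r <- element_radius(el)
    s <- stage(make_fixture("single_atom", element = el)$frames[[1L]])
    m <- afmscan::scan(s, afm_tip(1.0, 10), step = 0.05, margin = 0.8)
    expect_equal(max(m$heights), 2 * r, tolerance = 0.05)
  }
})

test_that("scan of a union is the pixelwise max of part scans", {
  set.seed(8)
  u <- random_staged(12, seed = 31)
  a <- u$atoms
  half <- seq_len(6L)
  sA <- afm_structure(a$element[half], a$x[half], a$y[half], a$z[half],
                      radius = a$radius[half])
  sB <- afm_structure(a$element[-half], a$x[-half], a$y[-half], a$z[-half],
                      radius = a$radius[-half])
  g <- build_grid(u, step = 0.2, margin = 1)
  tip <- afm_tip(0.8, 12)
  hu <- afmscan::scan(u, tip, g)$heights
  ha <- afmscan::scan(sA, tip, g)$heights
  hb <- afmscan::scan(sB, tip, g)$heights
  expect_identical(hu, pmax(ha, hb))
})

test_that("full maps match the brute-force oracle", {
  tip <- afm_tip(0.5, 10)
  for (seed in c(2, 17)) {
    s <- random_staged(10, seed = seed)
    g <- build_grid(s, step = 0.15, margin = 0.3)
    m <- afmscan::scan(s, tip, g)
    expect_lt(max(abs(m$heights - oracle_scan(s, tip, g))), 1e-3)
  }
})

test_that("heights are pointwise monotone in R and in alpha", {
  s <- random_staged(10, seed = 23)
  g <- build_grid(s, step = 0.2, margin = 1.5)
  for (al in c(5, 10, 15)) {
    maps <- lapply(c(0.5, 1.0, 1.5), function(R)
      afmscan::scan(s, afm_tip(R, al), g)$heights)
    expect_true(all(maps[[2L]] >= maps[[1L]] - 1e-12))
    expect_true(all(maps[[3L]] >= maps[[2L]] - 1e-12))
  }
  for (R in c(0.5, 1.0, 1.5)) {
    maps <- lapply(c(5, 10, 15), function(al)
      afmscan::scan(s, afm_tip(R, al), g)$heights)
    expect_true(all(maps[[2L]] >= maps[[1L]] - 1e-12))
    expect_true(all(maps[[3L]] >= maps[[2L]] - 1e-12))
  }
})

test_that("small-R, small-alpha limit approaches spherical dilation", {
  s <- random_staged(6, seed = 3)
  g <- build_grid(s, step = 0.2, margin = 0.5)
  tip <- afm_tip(R = 0.05, alpha_deg = 0.5)
  m <- afmscan::scan(s, tip, g)$heights
  # sphere branch alone (dilation by R + r), clamped at the stage
  a <- s$atoms
  xs <- grid_centers(g)$x; ys <- grid_centers(g)$y
  ref <- matrix(0, g$ny, g$nx)
  for (i in seq_len(nrow(a))) {
    rr <- tip$R + a$radius[i]
    d2 <- outer((ys - a$y[i])^2, (xs - a$x[i])^2, `+`)
    hi <- a$z[i] - tip$R + sqrt(pmax(rr^2 - d2, 0))
    hi[d2 > rr^2] <- 0
    ref <- pmax(ref, hi)
  }
  inside <- ref > 0
  expect_lt(max(abs(m[inside] - ref[inside])), 0.02)
})

test_that("a 90-degree rotation about z rotates the map", {
  s <- random_staged(10, seed = 77)
  a <- s$atoms
  ctr <- c(mean(a$x), mean(a$y))
  N <- 41L; stp <- 0.1
  g <- afm_grid(ctr[1L] - 20 * stp, ctr[2L] - 20 * stp, stp, N, N)
  tip <- afm_tip(0.6, 12)
  h1 <- afmscan::scan(s, tip, g)$heights
  h2 <- afmscan::scan(orient(s, euler_zyz(90, 0, 0)), tip, g)$heights
  expect_lt(max(abs(h2 - t(h1)[, N:1])), 1e-9)
})

test_that("coarse grids subsample the fine surface exactly", {
  s <- random_staged(10, seed = 5)
  gf <- build_grid(s, step = 0.5, margin = 1)
  # coarse grid sharing the same origin: every other fine centre
  nxc <- as.integer(floor((gf$nx - 1L) / 2L) + 1L)
  nyc <- as.integer(floor((gf$ny - 1L) / 2L) + 1L)
  gc <- afm_grid(gf$x0, gf$y0, 1.0, nxc, nyc)
  tip <- afm_tip(1, 10)
  hf <- afmscan::scan(s, tip, gf)$heights
  hc <- afmscan::scan(s, tip, gc)$heights
  expect_identical(hc, hf[seq(1L, by = 2L, length.out = nyc),
                          seq(1L, by = 2L, length.out = nxc)])
})

test_that("height map text export round-trips bit-exactly", {
  s <- random_staged(8, seed = 19)
  m <- afmscan::scan(s, afm_tip(1, 10), step = 0.3, margin = 1)
  f <- withr::local_tempfile(fileext = ".txt")
  write_heightmap(m, f, meta = c(R_nm = "1", alpha_deg = "10"))
  m2 <- read_heightmap(f)
  expect_identical(m2$heights, m$heights)
  expect_identical(m2$grid$step, m$grid$step)
  expect_identical(m2$grid$x0, m$grid$x0)
  expect_identical(attr(m2, "meta")[["R_nm"]], "1")
})

test_that("heightmap constructor enforces its invariants", {
  g <- afm_grid(0, 0, 1, 3, 2)
  expect_error(afm_heightmap(g, matrix(0, 3, 3)), "ny x nx")
  expect_error(afm_heightmap(g, matrix(-1, 2, 3)), ">= 0")
  expect_error(afm_heightmap(g, matrix(NaN, 2, 3)), "finite")
})
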
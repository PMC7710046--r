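ramp_raster <- function(ny = 12, nx = 16, ps = 1) {
  afm_raster(outer(seq_len(ny), seq_len(nx), function(j, i) 2 * i + 3 * j),
             ps)
}

test_that("gaussian_blur: identity at sigma 0, normalization, impulse", {
  r <- ramp_raster()
  expect_identical(gaussian_blur(r, 0)$pixels, r$pixels)
  expect_error(gaussian_blur(r, -1), "non-negative")

  const <- afm_raster(matrix(3.5, 20, 20), 1)
  expect_lt(max(abs(gaussian_blur(const, 2)$pixels - 3.5)), 1e-12)

  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  b <- gaussian_blur(afm_raster(imp, 1), 2)$pixels
  s <- 2; rad <- ceiling(4 * s)
  k <- exp(-(-rad:rad)^2 / (2 * s^2)); k <- k / sum(k)
  # the 2-D response is the separable product k[i] * k[j]
  expect_equal(b[21, 21 + (-rad:rad)], k * k[rad + 1L], tolerance = 1e-12)
  expect_equal(b[21 + (-rad:rad), 21], k * k[rad + 1L], tolerance = 1e-12)
  expect_equal(b[21 + (-rad:rad), 21 + (-rad:rad)], outer(k, k),
               tolerance = 1e-12)
  expect_equal(sum(b), 1, tolerance = 1e-12)
})

test_that("gaussian_blur commutes with constants and contracts the range", {
  set.seed(14)
  p <- matrix(stats::runif(30 * 25), 30, 25)
  r <- afm_raster(p, 0.5)
  b1 <- gaussian_blur(r, 1)$pixels
  b2 <- gaussian_blur(afm_raster(p + 7, 0.5), 1)$pixels
  expect_equal(b2, b1 + 7, tolerance = 1e-12)
  expect_lte(max(b1), max(p) + 1e-12)
  expect_gte(min(b1), min(p) - 1e-12)
  # sigma is physical: halving pixel_size doubles the pixel-space kernel
  fine <- gaussian_blur(afm_raster(p, 0.25), 1)$pixels
  expect_false(isTRUE(all.equal(fine, b1)))
})

test_that("resample: identity, constants, affine exactness", {
  r <- ramp_raster(ny = 10, nx = 14, ps = 2)
  same <- resample(r, 2)
  expect_equal(same$pixels, r$pixels, tolerance = 1e-12)

  const <- afm_raster(matrix(4, 9, 9), 1)
  for (f in c(0.4, 1.7)) {
    out <- resample(const, f)
    expect_lt(max(abs(out$pixels - 4)), 1e-12)
  }

  # bilinear reproduces an affine field exactly, including at borders
  out <- resample(r, 0.8)
  ny2 <- nrow(out$pixels); nx2 <- ncol(out$pixels)
  jj <- ((seq_len(ny2) - 0.5) * 0.8) / 2 + 0.5
  ii <- ((seq_len(nx2) - 0.5) * 0.8) / 2 + 0.5
  expect_equal(out$pixels, outer(jj, ii, function(j, i) 2 * i + 3 * j),
               tolerance = 1e-9)
  expect_error(resample(r, 1000), "fewer than 2")
})

test_that("clean_background thresholds strictly below the cut", {
  r <- afm_raster(matrix(c(0, 10, 10, 0), 2, 2), 1)
  out <- clean_background(r, 0.5)
  expect_equal(out$pixels, matrix(c(0, 10, 10, 0), 2, 2))
  expect_identical(out$mask, matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  # identity at threshold 0
  expect_identical(clean_background(r, 0)$pixels, r$pixels)
  expect_true(all(clean_background(r, 0)$mask))
  # all-equal image: nothing is strictly below the cut
  eq <- afm_raster(matrix(5, 3, 3), 1)
  expect_true(all(clean_background(eq, 0.5)$mask))
  # idempotence at a fixed threshold
  once <- clean_background(r, 0.5)
  twice <- clean_background(once, 0.5)
  expect_identical(twice$pixels, once$pixels)
  expect_identical(twice$mask, once$mask)
  expect_error(clean_background(r, 1), "\\[0, 1\\)")
})

test_that("correlation axioms", {
  set.seed(6)
  p <- matrix(stats::runif(64), 8, 8)
  a <- afm_raster(p, 1)
  expect_equal(correlation(a, a), 1.0)
  # affine invariance in either argument
  b <- afm_raster(2 * p + 3, 1)
  expect_equal(correlation(a, b), 1.0)
  expect_equal(correlation(b, a), 1.0)
  # symmetry
  q <- afm_raster(matrix(stats::runif(64), 8, 8), 1)
  expect_equal(correlation(a, q), correlation(q, a))
  expect_lte(abs(correlation(a, q)), 1)
  # perfect anticorrelation
  x <- afm_raster(matrix(c(0, 1, 1, 0), 2, 2), 1)
  y <- afm_raster(matrix(c(1, 0, 0, 1), 2, 2), 1)
  expect_equal(correlation(x, y), -1.0)
  # documented failure modes
  flat <- afm_raster(matrix(1, 8, 8), 1)
  expect_error(correlation(a, flat), "zero intensity variance")
  expect_error(correlation(a, afm_raster(matrix(1, 4, 4), 1)), "shape")
  tiny <- afm_raster(matrix(1:4, 2, 2), 1,
                     mask = matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_error(correlation(tiny, tiny), "fewer than 3")
  # cosine alternative
  expect_equal(correlation(a, a, method = "cosine"), 1.0)
})

test_that("ROI helpers: rectangle and mask file", {
  r <- ramp_raster(6, 6)
  rr <- set_roi(r, rect = c(2, 3, 4, 5))
  expect_equal(sum(rr$mask), 9L)
  expect_true(all(which(rr$mask, arr.ind = TRUE)[, 1L] %in% 3:5))
  f <- withr::local_tempfile(fileext = ".txt")
  m <- matrix(0L, 6, 6); m[1:2, ] <- 1L
  write.table(m, f, row.names = FALSE, col.names = FALSE)
  rm2 <- set_roi(r, mask_file = f)
  expect_equal(sum(rm2$mask), 12L)
  expect_error(set_roi(ramp_raster(3, 3), mask_file = f), "shape")
})

test_that("rasters round-trip through text and PNG readers", {
  s <- stage(make_fixture("dimer")$frames[[1L]])
  m <- afmscan::scan(s, afm_tip(0.5, 10), step = 0.1, margin = 0.5)
  f <- withr::local_tempfile(fileext = ".txt")
  write_heightmap(m, f)
  r <- read_raster(f)
  expect_identical(r$pixels, m$heights)
  expect_identical(r$pixel_size, m$grid$step)

  p <- withr::local_tempfile(fileext = ".png")
  render(m, p, colormap = "gray")
  rp <- read_raster(p, pixel_size = m$grid$step)
  expect_identical(dim(rp$pixels), dim(m$heights))
  # grayscale render encodes heights linearly: correlation ~ 1 up to the
  # 8-bit quantization of the PNG
  expect_gt(correlation(as_raster(m), rp), 0.999)
  expect_error(read_raster(p), "pixel_size")
})
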
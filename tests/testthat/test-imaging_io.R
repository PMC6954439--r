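test_that("stacks round-trip through TIFF with an explicit pixel size", {
  frames <- lapply(1:5, function(i) matrix(runif(64 * 64), 64, 64))
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(image_stack(frames, 0.1), path)
  st <- load_stack(path, pixel_size_override = 0.1)
  expect_length(st$frames, 5L)
  expect_identical(st$pixel_size, 0.1)
  expect_equal(st$frames[[3L]], frames[[3L]], tolerance = 1e-6)
})

test_that("pixel size resolution: override wins, missing metadata errors", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(16), 4, 4), path, bits.per.sample = 32L)
  expect_error(load_stack(path), "no pixel size")
  expect_equal(load_stack(path, pixel_size_override = 0.2)$pixel_size, 0.2)
  expect_error(load_stack(path, pixel_size_override = -0.1), "> 0")
  expect_error(load_stack("/nonexistent/file.tif", 0.1), "not found")
})

test_that("resolution metadata units convert to micrometres", {
  f <- matrix(0, 2, 2)
  attr(f, "x.resolution") <- 25400 / 0.1   # 0.1 um/px expressed per inch
  attr(f, "resolution.unit") <- "inch"
  expect_equal(mitoshape:::pixel_size_from_tiff(f), 0.1, tolerance = 1e-12)
  attr(f, "x.resolution") <- 10000 / 0.25
  attr(f, "resolution.unit") <- "cm"
  expect_equal(mitoshape:::pixel_size_from_tiff(f), 0.25, tolerance = 1e-12)
  attr(f, "resolution.unit") <- NULL
  attr(f, "x.resolution") <- 1 / 0.065
  attr(f, "description") <- "ImageJ=1.53\nunit=micron"
  expect_equal(mitoshape:::pixel_size_from_tiff(f), 0.065, tolerance = 1e-12)
  attr(f, "y.resolution") <- 2 * attr(f, "x.resolution")
  expect_error(mitoshape:::pixel_size_from_tiff(f), "anisotropic")
})

test_that("z-projection takes the per-pixel maximum and preserves calibration", {
  a <- matrix(c(3, 0, 1, 5), 2, 2)
  b <- matrix(c(7, 2, 0, 4), 2, 2)
  st <- image_stack(list(a, b), 0.1)
  pr <- z_project(st)
  expect_equal(pr$pixels, pmax(a, b))
  expect_equal(pr$pixels[1, 1], 7)
  expect_identical(pr$pixel_size, 0.1)
  # single-frame identity; permutation invariance; all-zero stacks
  expect_equal(z_project(image_stack(list(a), 0.1))$pixels, a)
  expect_equal(z_project(image_stack(list(b, a), 0.1))$pixels, pr$pixels)
  z <- matrix(0, 2, 2)
  expect_equal(z_project(image_stack(list(z, z), 0.1))$pixels, z)
})

test_that("cell-region masking zeroes outside the region and validates input", {
  px <- matrix(runif(100, 1, 2), 10, 10)
  img <- calibrated_image(px, 0.1)
  full <- cell_region(matrix(TRUE, 10, 10), "c1")
  expect_equal(apply_cell_region(img, full)$pixels, px)
  half <- matrix(FALSE, 10, 10); half[, 1:5] <- TRUE
  out <- apply_cell_region(img, cell_region(half, "c2"))
  expect_equal(out$pixels[, 1:5], px[, 1:5])
  expect_true(all(out$pixels[, 6:10] == 0))
  # idempotence
  expect_equal(apply_cell_region(out, cell_region(half, "c2"))$pixels,
               out$pixels)
  expect_error(cell_region(matrix(FALSE, 10, 10), "c3"), "empty")
  expect_error(apply_cell_region(img, cell_region(matrix(TRUE, 5, 5), "c4")),
               "dimensions")
})

test_that("calibrated images enforce their invariants", {
  expect_error(calibrated_image(matrix(-1, 2, 2), 0.1), "non-negative")
  expect_error(calibrated_image(matrix(NA_real_, 2, 2), 0.1), "finite")
  expect_error(calibrated_image(matrix(1, 2, 2), 0), "> 0")
  expect_error(image_stack(list(matrix(1, 2, 2), matrix(1, 3, 3)), 0.1),
               "same dimensions")
})

test_that("label masks and ImageJ ROIs both resolve to per-cell regions", {
  lab <- matrix(0, 32, 32); lab[3:10, 3:10] <- 1; lab[20:30, 15:25] <- 2
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(lab / 255, path, bits.per.sample = 8L)
  regions <- read_cell_regions(path)
  expect_length(regions, 2L)
  expect_equal(sum(regions[[1L]]$mask), 64L)
  expect_equal(sum(regions[[2L]]$mask), 11L * 11L)

  # rectangle ROI: ImageJ bounds [left,right) x [top,bottom)
  roi <- withr::local_tempfile(fileext = ".roi")
  write_ij_roi(roi, type = 1L, top = 4L, left = 6L, bottom = 12L, right = 16L)
  rg <- read_cell_regions(roi, dim = c(32L, 32L))[[1L]]
  expect_equal(sum(rg$mask), (12L - 4L) * (16L - 6L))
  expect_true(rg$mask[5L, 7L] && !rg$mask[4L, 7L])

  # polygon ROI: right triangle
  roi2 <- withr::local_tempfile(fileext = ".roi")
  write_ij_roi(roi2, type = 0L, top = 0L, left = 0L, bottom = 20L,
               right = 20L, x = c(0L, 20L, 0L), y = c(0L, 20L, 20L))
  rg2 <- read_cell_regions(roi2, dim = c(32L, 32L))[[1L]]
  expect_gt(sum(rg2$mask), 150)           # half of 20x20 up to rasterization
  expect_lt(sum(rg2$mask), 250)
  expect_true(rg2$mask[15L, 5L])           # deep inside the triangle
  expect_false(rg2$mask[5L, 15L])          # outside the hypotenuse
})
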
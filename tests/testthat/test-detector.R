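test_that("pixel-to-s mapping is radial and matches the two-step formula", {
  g <- small_detector(128L)
  bc <- g$beam_center
  expect_identical(s_of_pixel(g, bc[1], bc[2]), 0)
  expect_equal(s_of_pixel(g, bc[1] + 30, bc[2]),
               s_of_pixel(g, bc[1], bc[2] - 30))
  # independent scalar evaluation at a known radius
  r_mm <- 25 * g$pixel_pitch
  theta <- atan(r_mm / g$camera_length)
  lam <- electron_wavelength(g$accel_voltage)
  expect_equal(s_of_pixel(g, bc[1] + 25, bc[2]),
               4 * pi / lam * sin(theta / 2), tolerance = 1e-12)
})

test_that("noiseless render conserves counts and round trips through radial average", {
  g <- small_detector(256L)
  curve <- smooth_curve()
  img <- render_image(curve, g, total_counts = 1e7, seed = NULL)
  expect_equal(sum(img$counts[img$mask]), 1e7, tolerance = 1e-6)

  avg <- radial_average(img, bin_width = 0.02)
  # compare shapes after normalizing each to unit mean on common support
  ref <- approx(curve$s, curve$values, xout = avg$s)$y
  expect_lt(rel_rms(avg$values / mean(avg$values), ref / mean(ref)), 0.005)

  # render -> average -> render stability: the second render's usable area
  # is the averaged curve's support, so match the flux over that region
  S <- plumediff:::.pixel_s_matrix(g)
  common <- img$mask & (S <= max(avg$s))
  img2 <- render_image(avg, g, total_counts = sum(img$counts[common]),
                       seed = NULL)
  expect_lt(max(abs(img2$counts[common] - img$counts[common])) /
              max(img$counts[common]), 0.005)
})

test_that("Poisson sampling is seeded, reproducible, and calibrated", {
  g <- detector_geometry(n_pixels = c(100L, 100L), pixel_pitch = 0.58,
                         camera_length = 500)
  flat <- diffraction_curve(s_grid(11, 0.02), rep(1, length(s_grid(11, 0.02))))
  m <- 100
  img1 <- render_image(flat, g, total_counts = m * 100^2, seed = 5)
  img2 <- render_image(flat, g, total_counts = m * 100^2, seed = 5)
  img3 <- render_image(flat, g, total_counts = m * 100^2, seed = 6)
  expect_identical(img1$counts, img2$counts)
  expect_false(identical(img1$counts, img3$counts))
  expect_true(all(img1$counts == round(img1$counts)))
  # variance-to-mean ratio over ~1e4 usable pixels at expectation ~100
  noiseless <- render_image(flat, g, total_counts = m * 100^2, seed = NULL)
  use <- noiseless$mask & noiseless$counts > 0
  dev2 <- (img1$counts[use] - noiseless$counts[use])^2 / noiseless$counts[use]
  expect_gt(length(dev2), 5e3)
  expect_gt(mean(dev2), 0.9)
  expect_lt(mean(dev2), 1.1)
})

test_that("zero curve renders to an all-zero image for any seed", {
  g <- small_detector(64L)
  z <- diffraction_curve(s_grid(11, 0.02), numeric(length(s_grid(11, 0.02))))
  expect_true(all(render_image(z, g, 100, seed = 3)$counts == 0))
  expect_true(all(render_image(z, g, 100, seed = NULL)$counts == 0))
})

test_that("radial average handles uniform images, masks, and empty input", {
  g <- small_detector(128L)
  uni <- detector_image(matrix(7, 128, 128), g)
  avg <- radial_average(uni, bin_width = 0.05)
  expect_true(all(abs(avg$values - 7) < 1e-12))

  # isotropy: masking a quadrant leaves the high-count average unchanged
  curve <- smooth_curve()
  img <- render_image(curve, g, total_counts = 5e7, seed = 21)
  mask <- img$mask
  mask[1:64, 1:64] <- FALSE
  masked <- detector_image(img$counts, g, mask, meta = img$meta)
  a1 <- radial_average(img, bin_width = 0.1)
  a2 <- radial_average(masked, bin_width = 0.1)
  common <- intersect(round(a1$s, 6), round(a2$s, 6))
  i1 <- match(common, round(a1$s, 6)); i2 <- match(common, round(a2$s, 6))
  expect_lt(rel_rms(a2$values[i2], a1$values[i1]), 0.02)

  allmask <- detector_image(matrix(1, 8, 8),
                            detector_geometry(n_pixels = c(8L, 8L),
                                              pixel_pitch = 1,
                                              camera_length = 100),
                            mask = matrix(FALSE, 8, 8))
  expect_error(radial_average(allmask), "fully masked")
})

test_that("beam-center refinement recovers a known offset", {
  g <- small_detector(128L)
  curve <- smooth_curve()
  img <- render_image(curve, g, total_counts = 1e7, seed = NULL)
  truth <- g$beam_center
  found <- find_center(img, initial = truth + c(2.5, -1.5))
  expect_lt(max(abs(found - truth)), 0.5)
  expect_true(attr(found, "refined"))

  centered <- find_center(img, initial = truth)
  expect_lt(max(abs(centered - truth)), 0.5)

  flat_img <- detector_image(matrix(3, 128, 128), g)
  expect_warning(res <- find_center(flat_img, initial = truth),
                 "no radial structure")
  expect_identical(as.numeric(res), as.numeric(truth))
  expect_false(attr(res, "refined"))
})

test_that("detector images round trip through TIFF and text formats", {
  g <- small_detector(64L)
  curve <- smooth_curve()
  img <- render_image(curve, g, total_counts = 2e5, seed = 9)

  tif <- withr::local_tempfile(fileext = ".tif")
  write_image(img, tif)
  back <- read_image(tif)
  expect_equal(back$counts, img$counts)
  expect_equal(back$geometry$beam_center, g$beam_center)
  expect_equal(back$geometry$pixel_pitch, g$pixel_pitch)

  txt <- withr::local_tempfile(fileext = ".dat")
  write_image(img, txt)
  back2 <- read_image(txt)
  expect_equal(back2$counts, img$counts)
})

test_that("curves round trip through two-column text files", {
  c1 <- smooth_curve()
  path <- withr::local_tempfile(fileext = ".dat")
  write_curve(c1, path)
  back <- read_curve(path)
  expect_equal(back$s, c1$s)
  expect_equal(back$values, c1$values, tolerance = 1e-12)
  expect_equal(back$role, c1$role)
})
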
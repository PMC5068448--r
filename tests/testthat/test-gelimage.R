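test_that("loading normalises by bit depth and counts saturation", {
  p8 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(1, 20, 20), p8)           # every pixel at 255
  g8 <- load_gel(p8)
  expect_true(all(g8$raster == 1))
  expect_equal(g8$saturation_fraction, 1)
  expect_equal(g8$bit_depth, 8L)

  p16 <- withr::local_tempfile(fileext = ".tif")
  m <- matrix(0.5, 100, 100)
  m[37, 53] <- 1                                  # one pixel at 65535
  tiff::writeTIFF(m, p16, bits.per.sample = 16)
  g16 <- load_gel(p16)
  expect_equal(g16$bit_depth, 16L)
  expect_equal(g16$saturation_fraction, 1e-4)

  expect_error(load_gel("does-not-exist.tif"), class = "gelquant_io_error")
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("x", bad)
  expect_error(load_gel(bad), class = "gelquant_io_error")
})

test_that("a rendered gel survives a TIFF write/read round trip bit-exactly", {
  path <- withr::local_tempfile(fileext = ".tif")
  write_gel(default_sg$gel, path)
  back <- load_gel(path)
  expect_identical(back$raster, default_sg$gel$raster)
})

test_that("inversion complements intensities exactly once", {
  g <- gel_image(matrix(0.2, 10, 10))
  expect_equal(invert_gel(g)$raster[1, 1], 0.8)
  expect_error(invert_gel(invert_gel(g)), class = "gelquant_state_error")

  half <- gel_image(matrix(0.5, 10, 10))
  expect_equal(invert_gel(half)$raster, half$raster)

  set.seed(7)
  m <- matrix(runif(400, 0, 0.4), 20, 20)   # skewed so no heuristic warning
  g2 <- gel_image(1 - m)
  expect_equal(mean(invert_gel(g2)$raster), 1 - mean(g2$raster))
})

test_that("leveling rotates by the reference angle and is identity when level", {
  set.seed(11)
  m <- matrix(runif(300 * 200), 300, 200)
  g <- gel_image(m)
  lev <- level_gel(g, c(100, 30), c(100, 170))
  expect_identical(lev$raster, m)            # bitwise no-op
  expect_equal(lev$rotation_applied, 0)
  expect_true(lev$leveled)

  tilted <- level_gel(g, c(100, 30), c(110, 170))
  expect_equal(tilted$rotation_applied, atan2(10, 140) * 180 / pi)
  expect_true(all(tilted$raster >= 0 & tilted$raster <= 1))

  expect_error(level_gel(g, c(100, 30), c(110, 30)),
               class = "gelquant_geometry_error")
})

test_that("leveling brings a skewed gel's top ladder bands onto one row", {
  spec <- synthetic_gel_spec(skew_deg = 1.5, seed = 5)
  sg <- render_gel(spec)
  boxes <- spec_lane_boxes(spec, sg$gel)
  sc <- score_gel(sg$gel, boxes)
  # rendered 23 kb centres differ across the gel before leveling
  pre_diff <- abs(diff(sg$truth$band_rows["23130", c("ladder1", "ladder2")]))
  expect_gt(pre_diff, 5)
  # after the pipeline's leveling, re-detected 23 kb apexes agree
  post_diff <- abs(sc$ladder_peaks$left$row[1] - sc$ladder_peaks$right$row[1])
  expect_lte(post_diff, 1)
})

test_that("background subtraction removes smooth fields and keeps bands", {
  flat <- gel_image(matrix(0.3, 200, 200), inverted = TRUE)
  out <- subtract_background(flat)
  expect_true(all(out$raster == 0))
  expect_error(subtract_background(flat, ball_radius = -1),
               class = "gelquant_parameter_error")
  expect_error(subtract_background(gel_image(matrix(0.3, 50, 50))),
               class = "gelquant_state_error")

  # constant background + one sharp full-width band: band preserved
  band_center <- 150
  band <- 0.4 * exp(-(seq_len(300) - band_center)^2 / (2 * 3^2))
  img <- matrix(0.3, 300, 240) + band
  sub <- subtract_background(gel_image(pmin(img, 1), inverted = TRUE))
  prof <- rowMeans(sub$raster)
  expect_equal(prof[band_center], 0.4, tolerance = 0.02 * 0.4 / 0.4)
  expect_lt(max(prof[c(1:100, 200:300)]), 0.01)
})

test_that("background subtraction is idempotent within 1e-3", {
  g1 <- subtract_background(invert_gel(default_sg$gel))
  g2 <- subtract_background(g1)
  expect_lt(max(abs(g2$raster - g1$raster)), 1e-3)
})

test_that("a smooth vignette shifts scores by less than one point", {
  spec_v <- synthetic_gel_spec(seed = 9)
  spec_f <- synthetic_gel_spec(vignette_amp = 0, seed = 9)
  sc_v <- score_gel(render_gel(spec_v)$gel,
                    spec_lane_boxes(spec_v, render_gel(spec_v)$gel))
  sc_f <- score_gel(render_gel(spec_f)$gel,
                    spec_lane_boxes(spec_f, render_gel(spec_f)$gel))
  expect_lt(max(abs(sc_v$quantification$percent_above -
                      sc_f$quantification$percent_above)), 1)
})

test_that("gel_image enforces its invariants", {
  expect_error(gel_image(matrix(1.5, 5, 5)), class = "gelquant_image_error")
  expect_error(gel_image(matrix(0.5, 5, 5), background_subtracted = TRUE),
               class = "gelquant_image_error")
})
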
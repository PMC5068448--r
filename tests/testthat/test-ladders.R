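test_that("built-in HindIII ladder carries the seven visible bands", {
  lad <- builtin_ladder("hindiii")
  expect_identical(lad$band_sizes, c(23130, 9416, 6557, 4361, 2322, 2027, 564))
  expect_true(9416 %in% lad$threshold_candidates)
  expect_false(564 %in% lad$threshold_candidates)
  expect_true(all(lad$threshold_candidates %in% lad$band_sizes))
  expect_error(builtin_ladder("foo"), class = "gelquant_catalog_error")
  expect_true("hindiii" %in% list_ladders())
})

test_that("ladder definitions enforce decreasing positive band sizes", {
  expect_error(ladder_definition("x", c(100, 200)),
               class = "gelquant_ladder_error")
  expect_error(ladder_definition("x", c(200, -5)),
               class = "gelquant_ladder_error")
  expect_error(ladder_definition("x", c(200, 100), threshold_candidates = 50),
               class = "gelquant_ladder_error")
})

test_that("user ladders load from the catalogue JSON format", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"name": "custom", "band_sizes_bp": [10000, 5000, 1000]}', path)
  lad <- read_ladder(path)
  expect_identical(lad$band_sizes, c(10000, 5000, 1000))
  expect_identical(lad$threshold_candidates, lad$band_sizes)
})

test_that("migration model fits a log-linear law through matched bands", {
  # two points determine the line
  m2 <- fit_migration_model(c(10, 100), c(23130, 564))
  expect_equal(as.numeric(position_of_size(m2, 564)), 100, tolerance = 1e-9)
  expect_equal(as.numeric(position_of_size(m2, 23130)), 10, tolerance = 1e-9)

  # exact-fit case: all seven bands on a perfect log-linear law
  sizes <- builtin_ladder("hindiii")$band_sizes
  pos <- 1200 - 240 * log10(sizes)
  m7 <- fit_migration_model(pos, sizes)
  expect_lt(max(abs(m7$residuals)), 1e-9)

  # fit invariant to the order in which pairs are supplied
  shuffle <- c(4, 1, 7, 3, 6, 2, 5)
  m7b <- fit_migration_model(pos[shuffle], sizes[shuffle])
  expect_equal(m7$coefficients, m7b$coefficients, tolerance = 1e-12)

  expect_error(fit_migration_model(c(10, 5), c(23130, 564)),
               class = "gelquant_calibration_error")
  expect_error(fit_migration_model(100, 564),
               class = "gelquant_calibration_error")
})

test_that("size and position are mutually inverse and monotone", {
  sizes <- builtin_ladder("hindiii")$band_sizes
  m <- fit_migration_model(1200 - 240 * log10(sizes), sizes)

  expect_equal(as.numeric(size_at_position(m, position_of_size(m, 4361))),
               4361, tolerance = 1e-6)
  grid <- exp(seq(log(564), log(23130), length.out = 1000))
  d <- as.numeric(position_of_size(m, grid))
  expect_true(all(diff(d) < 0))
  expect_equal(as.numeric(size_at_position(m, d)), grid, tolerance = 1e-6)

  # geometric mean of two calibration sizes lands at the position midpoint
  gm <- sqrt(23130 * 564)
  expect_equal(as.numeric(position_of_size(m, gm)),
               mean(as.numeric(position_of_size(m, c(23130, 564)))),
               tolerance = 1e-9)

  expect_error(position_of_size(m, -1), class = "gelquant_domain_error")
  expect_warning(position_of_size(m, 50), "extrapolating")
  expect_true(attr(position_of_size(m, 50, warn_extrapolation = FALSE),
                   "extrapolated"))
  far <- as.numeric(position_of_size(m, 564)) + 200
  expect_true(attr(size_at_position(m, far), "extrapolated"))
})

test_that("calibration recovers the simulator's generating coefficients", {
  prof <- extract_profile(
    subtract_background(invert_gel(default_sg$gel)), default_boxes[[1]])
  peaks <- find_band_peaks(prof, builtin_ladder("hindiii"))
  ok <- !is.na(peaks$assigned_size)
  expect_gte(sum(ok), 6)
  m <- fit_migration_model(peaks$row[ok], peaks$assigned_size[ok])
  expect_equal(unname(m$coefficients["a"]),
               unname(default_spec$migration[["a"]]), tolerance = 0.01)
  expect_equal(unname(m$coefficients["b"]),
               unname(default_spec$migration[["b"]]), tolerance = 0.01)

  # band positions and back-calculated sizes track the rendered truth
  truth_rows <- default_sg$truth$band_rows[, "ladder1"]
  expect_lt(max(abs(as.numeric(position_of_size(m, 9416)) -
                      truth_rows["9416"])), 2)
  est_sizes <- as.numeric(size_at_position(m, truth_rows))
  expect_lt(max(abs(est_sizes / as.numeric(names(truth_rows)) - 1)), 0.03)
})
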
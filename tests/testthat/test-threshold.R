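hindiii <- builtin_ladder("hindiii")

make_profile <- function(values, row_top = 1, label = "t",
                         role = "ladder") {
  g <- gel_image(matrix(rep(pmin(values, 1), 5), length(values), 5,
                        byrow = FALSE))
  lane <- define_lane(g, 3, 5, row_top, row_top + length(values) - 1,
                      role = role, label = label)
  extract_profile(g, lane)
}

test_that("ladder peaks are found and assigned in order", {
  gel <- subtract_background(invert_gel(default_sg$gel))
  prof <- extract_profile(gel, default_boxes[[1]])
  peaks <- find_band_peaks(prof, hindiii)
  assigned <- peaks[!is.na(peaks$assigned_size), ]
  expect_equal(nrow(assigned), 7)
  expect_identical(assigned$assigned_size, hindiii$band_sizes)
  truth <- default_sg$truth$band_rows[, "ladder1"]
  expect_lt(max(abs(assigned$row - truth[as.character(assigned$assigned_size)])),
            2)
})

test_that("a single-peak profile raises a ladder-call error", {
  v <- 0.01 + 0.5 * exp(-(1:200 - 80)^2 / 18)
  expect_error(find_band_peaks(make_profile(v), hindiii),
               class = "gelquant_ladder_call_error")
})

test_that("equal-height candidates resolve to the model-expected position", {
  lad2 <- ladder_definition("two", c(20000, 1000))
  v <- numeric(400) + 0.01
  v[100] <- 0.5; v[120] <- 0.5; v[300] <- 0.5
  model <- fit_migration_model(c(108, 300), c(20000, 1000))
  peaks <- find_band_peaks(make_profile(v), lad2, model = model)
  expect_equal(peaks$row[peaks$assigned_size %in% 20000], 100)
  expect_equal(peaks$row[peaks$assigned_size %in% 1000], 300)
})

test_that("threshold apex lookup honours assignment", {
  gel <- subtract_background(invert_gel(default_sg$gel))
  peaks <- find_band_peaks(extract_profile(gel, default_boxes[[1]]), hindiii)
  apex <- apex_of_threshold_band(peaks, 9416)
  expect_lt(abs(apex - default_sg$truth$band_rows["9416", "ladder1"]), 2)

  dropped <- peaks[peaks$assigned_size %in% c(23130, 564) |
                     is.na(peaks$assigned_size), ]
  attr(dropped, "lane_label") <- "lad"
  expect_error(apex_of_threshold_band(dropped, 9416),
               class = "gelquant_threshold_error")
})

test_that("threshold rows interpolate linearly between the ladder apexes", {
  spec_level <- threshold_spec(hindiii, 9416, 210, 210, 50, 450)
  expect_equal(threshold_row_for_lane(spec_level, 120), 210)
  expect_equal(threshold_row_for_lane(spec_level, 430), 210)

  spec_tilt <- threshold_spec(hindiii, 9416, 200, 220, 50, 450)
  expect_equal(threshold_row_for_lane(spec_tilt, 250), 210)
  expect_equal(threshold_row_for_lane(spec_tilt, 50), 200)
  expect_error(threshold_row_for_lane(spec_tilt, 30),
               class = "gelquant_bracketing_error")
  expect_error(threshold_spec(hindiii, 5000, 200, 220, 50, 450),
               class = "gelquant_threshold_error")
})

test_that("closing records closure without changing values or area", {
  ends_zero <- close_profile(make_profile(c(0.2, 0.5, 0.3, 0)))
  expect_true(ends_zero$closed)
  expect_false(ends_zero$closure_applied)

  open_tail <- make_profile(c(0.2, 0.5, 0.4, 0.3))
  closed <- close_profile(open_tail)
  expect_true(closed$closure_applied)
  expect_identical(closed$values, open_tail$values)
  a <- integrate_regions(closed, 2)
  expect_equal(sum(a), sum((open_tail$values[-1] + open_tail$values[-4]) / 2))
})

test_that("artifact masking replaces a chord and removes exact area", {
  flat <- close_profile(make_profile(rep(0.2, 100)))
  masked <- mask_artifact(flat, 30, 60)
  expect_equal(masked$values, flat$values)
  expect_length(masked$mask_segments, 1)

  # triangular spur of known area on a flat baseline
  v <- rep(0.1, 101)
  spur <- 40:60
  v[spur] <- 0.1 + 0.3 * (1 - abs(spur - 50) / 10)
  spur_area <- sum((v[-1] + v[-101]) / 2) - 0.1 * 100
  prof <- close_profile(make_profile(v))
  masked <- mask_artifact(prof, 40, 60)
  expect_equal(sum(masked$values - 0.1), 0, tolerance = 1e-12)
  before <- integrate_regions(prof, 80)
  after <- integrate_regions(masked, 80)
  expect_equal(sum(before) - sum(after), spur_area, tolerance = 1e-12)

  expect_error(mask_artifact(prof, 60, 40), class = "gelquant_parameter_error")
  expect_error(mask_artifact(prof, 90, 150), class = "gelquant_parameter_error")
})

test_that("integration splits the shared trapezoid at the threshold row", {
  const <- close_profile(make_profile(rep(0.4, 101)))
  areas <- integrate_regions(const, 51)
  expect_equal(areas[["area_above"]], areas[["area_below"]],
               tolerance = 0.4 / sum(areas))

  # all intensity strictly above the threshold row
  v <- c(0.5, 0.5, 0.5, 0, 0, 0, 0)
  top_heavy <- close_profile(make_profile(v))
  expect_equal(integrate_regions(top_heavy, 5)[["area_below"]], 0)

  # conservation is exact (to float arithmetic) at any threshold
  set.seed(21)
  prof <- close_profile(make_profile(runif(100, 0, 0.8)))
  total <- sum((prof$values[-1] + prof$values[-100]) / 2)
  for (t_row in c(10, 33.25, 71.5)) {
    a <- integrate_regions(prof, t_row)
    expect_equal(a[["area_above"]] + a[["area_below"]], total,
                 tolerance = 1e-12)
  }
  expect_error(integrate_regions(prof, 200),
               class = "gelquant_parameter_error")
  expect_error(integrate_regions(make_profile(v), 3),
               class = "gelquant_state_error")
})

test_that("percent above threshold is the area ratio with guarded edges", {
  expect_equal(percent_above_threshold(72, 28), 72)
  expect_equal(percent_above_threshold(0, 5), 0)
  expect_equal(percent_above_threshold(5, 0), 100)
  expect_warning(res <- percent_above_threshold(0, 0), "empty lane")
  expect_true(is.na(res))
  expect_error(percent_above_threshold(-1, 2),
               class = "gelquant_internal_error")
})

test_that("score_gel recovers known fractions and is deterministic", {
  truth <- default_sg$truth$percent_above[, "9416"]
  est <- default_score$quantification$percent_above
  expect_lt(max(abs(est - truth)), 3)

  again <- score_gel(default_sg$gel, default_boxes)
  expect_identical(again$quantification, default_score$quantification)
})

test_that("score_gel requires bracketing ladder lanes", {
  g <- default_sg$gel
  boxes <- default_boxes
  # move the left ladder to the right of the first sample lane
  no_left <- boxes[-1]
  expect_error(score_gel(g, no_left), class = "gelquant_bracketing_error")
})

test_that("scores are invariant to intensity scaling of a subtracted gel", {
  gel <- subtract_background(invert_gel(default_sg$gel))
  gel <- level_gel(gel, c(100, 60), c(100, 420))   # mark level, no-op
  scaled <- gel
  scaled$raster <- 0.37 * gel$raster
  scaled$residual <- 0.37 * gel$residual
  a <- score_gel(gel, default_boxes, level = FALSE)
  b <- score_gel(scaled, default_boxes, level = FALSE)
  expect_equal(a$quantification$percent_above,
               b$quantification$percent_above, tolerance = 1e-9)
})

test_that("an empty lane yields a flagged NA percent", {
  spec <- synthetic_gel_spec(lane_mass = c(12, 0, 12, 12), noise_sd = 0,
                             vignette_amp = 0, quantize = FALSE, seed = 2)
  sg <- render_gel(spec)
  sc <- score_gel(sg$gel, spec_lane_boxes(spec, sg$gel))
  q <- sc$quantification
  expect_true(is.na(q$percent_above[q$label == "sample2"]))
  expect_match(q$warnings[q$label == "sample2"], "empty-lane")
  expect_false(anyNA(q$percent_above[q$label != "sample2"]))
})

test_that("masking an injected speck restores the unmasked score", {
  spec_sp <- synthetic_gel_spec(
    specks = list(list(row = 400, col = 204, amplitude = 0.3, width = 4)),
    seed = 1)
  sg_sp <- render_gel(spec_sp)
  boxes <- spec_lane_boxes(spec_sp, sg_sp$gel)
  clean <- default_score$quantification$percent_above[2]
  unmasked <- score_gel(sg_sp$gel, boxes)$quantification$percent_above[2]
  masked <- score_gel(sg_sp$gel, boxes,
                      masks = list(sample2 = list(c(380, 420))))
  expect_gt(abs(unmasked - clean), 1)   # the speck matters
  expect_lt(abs(masked$quantification$percent_above[2] - clean), 1)
})
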
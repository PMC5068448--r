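# Core "greater than X kb" quantification: ladder band apexes, the
# interpolated DNA-threshold line, region closing, artifact masking,
# trapezoid integration and percent-above-threshold.

#' Detect and assign ladder band peaks in a profile
#'
#' Local maxima with prominence above `min_prominence_frac` of the profile
#' maximum are detected and assigned to the ladder's band sizes by an
#' order-preserving maximisation of total assigned peak height (larger
#' fragments migrate less, so sizes in decreasing order map to rows in
#' increasing order). When a migration model is supplied, candidate peaks
#' are restricted to a window of `window_frac` of the profile length around
#' the model-expected position, and among equal-height candidates the one
#' nearer the expected position wins.
#'
#' @param profile A ladder-lane [extract_profile()] result.
#' @param ladder A [ladder_definition()].
#' @param model Optional [fit_migration_model()] used for expected band
#'   positions.
#' @param min_prominence_frac Prominence floor as a fraction of the profile
#'   maximum (default 0.05).
#' @param window_frac Half-width of the expected-position window as a
#'   fraction of profile length (default 0.05); only used with `model`.
#' @return A `band_peaks` data frame with columns `row` (absolute pixels),
#'   `height`, `prominence`, `assigned_size` (bp, `NA` for unassigned
#'   peaks), and attributes `unassigned_bands` and `lane_label`.
#' @export
find_band_peaks <- function(profile, ladder, model = NULL,
                            min_prominence_frac = 0.05,
                            window_frac = 0.05) {
  v <- profile$values
  pk <- .find_peaks(v, min_prominence = min_prominence_frac * max(v))
  sizes <- ladder$band_sizes               # decreasing
  n_pk <- nrow(pk)
  n_bd <- length(sizes)
  rows_abs <- profile$rows[pk$index]
  expected <- if (!is.null(model)) {
    as.numeric(position_of_size(model, sizes, warn_extrapolation = FALSE))
  } else NULL
  window <- window_frac * length(v)
  eps <- 1e-6 * max(v) / max(1, length(v))

  # order-preserving assignment maximising total (height - tiny distance
  # penalty); bands may stay unassigned when peaks run out
  score <- function(j, i) {
    if (is.null(expected)) return(pk$height[i])
    d <- abs(rows_abs[i] - expected[j])
    if (d > window) return(-Inf)
    pk$height[i] - eps * d
  }
  f <- matrix(0, n_bd + 1L, n_pk + 1L)
  take <- matrix(FALSE, n_bd + 1L, n_pk + 1L)
  if (n_pk > 0L) {
    for (j in seq_len(n_bd)) {
      for (i in seq_len(n_pk)) {
        best <- max(f[j + 1L, i], f[j, i + 1L])
        s <- score(j, i)
        if (is.finite(s) && f[j, i] + s >= best) {
          best <- f[j, i] + s
          take[j + 1L, i + 1L] <- TRUE
        }
        f[j + 1L, i + 1L] <- best
      }
    }
  }
  assigned <- rep(NA_real_, n_pk)
  j <- n_bd; i <- n_pk
  while (j > 0L && i > 0L) {
    if (take[j + 1L, i + 1L]) {
      assigned[i] <- sizes[j]
      j <- j - 1L; i <- i - 1L
    } else if (f[j + 1L, i] >= f[j, i + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  n_assigned <- sum(!is.na(assigned))
  if (n_assigned < 2L) {
    .stop_gelquant(sprintf(
      "ladder call failed in lane '%s': only %d band(s) assignable",
      profile$lane$label, n_assigned), "gelquant_ladder_call_error")
  }
  out <- data.frame(row = rows_abs, height = pk$height,
                    prominence = pk$prominence, assigned_size = assigned)
  structure(out,
            unassigned_bands = sizes[!sizes %in% assigned],
            lane_label = profile$lane$label,
            class = c("band_peaks", "data.frame"))
}

#' Apex row of the threshold band
#'
#' @param peaks A [find_band_peaks()] result.
#' @param band_size Threshold band size in bp.
#' @return The assigned peak's row (pixels).
#' @export
apex_of_threshold_band <- function(peaks, band_size) {
  hit <- which(!is.na(peaks$assigned_size) & peaks$assigned_size == band_size)
  if (!length(hit)) {
    .stop_gelquant(sprintf(
      "threshold band %s bp not assigned in ladder lane '%s'",
      format(band_size, big.mark = ","),
      attr(peaks, "lane_label") %||% "?"), "gelquant_threshold_error")
  }
  peaks$row[hit[1L]]
}

#' Construct a DNA-threshold specification
#'
#' Records the threshold band and the apex rows found in the two bracketing
#' ladder lanes, from which the per-lane threshold line is interpolated.
#'
#' @param ladder A [ladder_definition()].
#' @param band_size Threshold band size in bp; must be a band of `ladder`.
#' @param left_apex_row,right_apex_row Apex rows in the left/right ladder.
#' @param left_lane_col,right_lane_col Ladder lane centre columns.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(ladder, band_size, left_apex_row, right_apex_row,
                           left_lane_col, right_lane_col) {
  if (!band_size %in% ladder$band_sizes) {
    .stop_gelquant(sprintf("%s bp is not a band of ladder '%s'",
                           format(band_size, big.mark = ","), ladder$name),
                   "gelquant_threshold_error")
  }
  if (left_lane_col >= right_lane_col) {
    .stop_gelquant("left ladder must lie left of the right ladder",
                   "gelquant_geometry_error")
  }
  structure(list(ladder_name = ladder$name, band_size = band_size,
                 left_apex_row = left_apex_row,
                 right_apex_row = right_apex_row,
                 left_lane_col = left_lane_col,
                 right_lane_col = right_lane_col),
            class = "threshold_spec")
}

#' Interpolated threshold row for a lane
#'
#' The DNA-threshold line runs straight from the left ladder's threshold
#' apex to the right ladder's; each sample lane's threshold row is the line
#' evaluated at the lane centre. Lanes outside the bracketing ladders are
#' refused.
#'
#' @param spec A [threshold_spec()].
#' @param lane_center_col Lane centre column, pixels.
#' @return Threshold row (possibly fractional), pixels.
#' @export
threshold_row_for_lane <- function(spec, lane_center_col) {
  if (lane_center_col < spec$left_lane_col ||
      lane_center_col > spec$right_lane_col) {
    .stop_gelquant(sprintf(
      "lane at column %g is not bracketed by the ladder lanes (%g, %g)",
      lane_center_col, spec$left_lane_col, spec$right_lane_col),
      "gelquant_bracketing_error")
  }
  frac <- (lane_center_col - spec$left_lane_col) /
    (spec$right_lane_col - spec$left_lane_col)
  spec$left_apex_row + (spec$right_apex_row - spec$left_apex_row) * frac
}

#' Close an intensity profile region
#'
#' Mirrors the manual close-the-region step: a region is made measurable by
#' a vertical drop at the final row. The drop adds no area, so values are
#' unchanged; whether closure was actually needed (terminal value above
#' `tol_frac` of the profile maximum) is recorded.
#'
#' @param profile A [extract_profile()] result.
#' @param tol_frac Closure tolerance as a fraction of the profile maximum.
#' @return The profile with `closed = TRUE` and `closure_applied` recorded.
#' @export
close_profile <- function(profile, tol_frac = 0.01) {
  v <- profile$values
  profile$closure_applied <- v[length(v)] > tol_frac * max(v)
  profile$closed <- TRUE
  profile
}

#' Mask an artifact peak with a straight chord
#'
#' Replaces the profile values strictly between `start_row` and `end_row`
#' with the straight line joining the values at those rows, reproducing the
#' manual elimination of erroneous peaks from gel flaws. The segment is
#' recorded in `mask_segments`.
#'
#' @param profile A [extract_profile()] result.
#' @param start_row,end_row Absolute rows, `start_row < end_row`, inside
#'   the profile extent.
#' @return The masked profile.
#' @export
mask_artifact <- function(profile, start_row, end_row) {
  r0 <- profile$rows[1L]
  rn <- profile$rows[length(profile$rows)]
  if (start_row >= end_row || start_row < r0 || end_row > rn) {
    .stop_gelquant("mask rows must satisfy row_top <= start < end <= row_bottom",
                   "gelquant_parameter_error")
  }
  i0 <- which(profile$rows == round(start_row))
  i1 <- which(profile$rows == round(end_row))
  v <- profile$values
  idx <- seq.int(i0, i1)
  v[idx] <- v[i0] + (v[i1] - v[i0]) * (idx - i0) / (i1 - i0)
  profile$values <- v
  profile$mask_segments <- c(profile$mask_segments,
                             list(c(round(start_row), round(end_row))))
  profile
}

#' Integrate a profile above and below the threshold row
#'
#' Trapezoidal integration of the closed profile over
#' `[row_top, threshold_row]` (fragments larger than the threshold size,
#' nearer the well) and `[threshold_row, row_bottom]`. The trapezoid
#' straddling the threshold row is split at the (possibly fractional)
#' threshold, so the threshold row's value is shared between the regions.
#' `area_below` is obtained as total minus `area_above`, making
#' conservation exact.
#'
#' @param profile A closed [close_profile()] profile.
#' @param threshold_row Threshold row (absolute pixels, may be fractional).
#' @return Named numeric vector `c(area_above, area_below)` in
#'   intensity-pixels.
#' @export
integrate_regions <- function(profile, threshold_row) {
  if (!isTRUE(profile$closed)) {
    .stop_gelquant("profile must be closed before integration (close_profile)",
                   "gelquant_state_error")
  }
  v <- profile$values
  r0 <- profile$rows[1L]
  rn <- profile$rows[length(profile$rows)]
  if (threshold_row < r0 || threshold_row > rn) {
    .stop_gelquant(sprintf(
      "threshold row %.1f outside the profile extent [%d, %d]",
      threshold_row, r0, rn), "gelquant_parameter_error")
  }
  u <- threshold_row - r0          # 0-based offset within profile
  i0 <- floor(u)
  frac <- u - i0
  total <- .trapz(v)
  above <- .trapz(v[seq_len(i0 + 1L)])
  if (frac > 0) {
    v_t <- v[i0 + 1L] + frac * (v[i0 + 2L] - v[i0 + 1L])
    above <- above + frac * (v[i0 + 1L] + v_t) / 2
  }
  c(area_above = above, area_below = max(total - above, 0))
}

#' Percent of DNA signal at or above the threshold
#'
#' @param area_above,area_below Region areas from [integrate_regions()].
#' @return `100 * area_above / (area_above + area_below)`, or `NA` with a
#'   warning when the lane is empty (zero total area).
#' @export
percent_above_threshold <- function(area_above, area_below) {
  if (area_above < 0 || area_below < 0) {
    .stop_gelquant("negative region area (internal invariant violation)",
                   "gelquant_internal_error")
  }
  total <- area_above + area_below
  if (total <= 0) {
    warning("empty lane: total area is zero; percent above threshold undefined")
    return(NA_real_)
  }
  100 * area_above / total
}

#' @noRd
.top_band_row <- function(profile) {
  pk <- .find_peaks(profile$values,
                    min_prominence = 0.25 * max(profile$values))
  if (!nrow(pk)) return(profile$rows[which.max(profile$values)])
  profile$rows[min(pk$index)]
}

#' Score a gel: full percent-above-threshold pipeline
#'
#' Runs the whole quantification: inversion (if needed), leveling on the
#' top ladder bands, background subtraction, per-lane profiles, ladder band
#' calls in the bracketing ladder lanes, the interpolated DNA-threshold
#' line, region closing, user-specified artifact masks, trapezoid
#' integration and the percent of signal at or above the threshold size.
#'
#' When several ladder-dilution lanes flank one side, the lane with the
#' most assigned bands is used; ties go to the brightest (least diluted)
#' lane.
#'
#' @param gel A [gel_image()] in any preprocessing state.
#' @param lanes List of [define_lane()] boxes; every sample lane must be
#'   bracketed by at least one ladder lane on each side.
#' @param ladder A [ladder_definition()] or catalogue name (default
#'   `"hindiii"`).
#' @param band_size Threshold band size in bp (default 9416).
#' @param masks Optional named list: `label -> list of c(start_row,
#'   end_row)` artifact chords, applied to the matching sample lane.
#' @param background_radius Disc radius for [subtract_background()].
#' @param closure_tol Tolerance for [close_profile()].
#' @param level Level the image on the top ladder bands first (default
#'   `TRUE`; skipped when `gel$leveled` is already set).
#' @param min_prominence_frac Peak prominence floor for ladder calls.
#' @return An object of class `gel_score`: list with `quantification`
#'   (data frame: `label`, `threshold_row`, `area_above`, `area_below`,
#'   `percent_above`, `warnings`), `threshold` ([threshold_spec()]),
#'   `model` ([fit_migration_model()]), `profiles`, `ladder_peaks`,
#'   `lanes`, and `params`.
#' @export
score_gel <- function(gel, lanes, ladder = "hindiii", band_size = 9416,
                      masks = NULL, background_radius = 50,
                      closure_tol = 0.01, level = TRUE,
                      min_prominence_frac = 0.05) {
  if (is.character(ladder)) ladder <- builtin_ladder(ladder)
  roles <- vapply(lanes, function(l) l$role, character(1))
  centers <- vapply(lanes, function(l) l$center_col, numeric(1))
  samples <- which(roles == "sample")
  ladders <- which(roles == "ladder")
  if (!length(samples)) {
    .stop_gelquant("no sample lanes supplied", "gelquant_geometry_error")
  }
  left_lads <- ladders[centers[ladders] < min(centers[samples])]
  right_lads <- ladders[centers[ladders] > max(centers[samples])]
  if (!length(left_lads) || !length(right_lads)) {
    .stop_gelquant(
      "samples must be bracketed by a ladder lane on each side",
      "gelquant_bracketing_error")
  }

  if (!gel$inverted) gel <- invert_gel(gel)
  if (level && !gel$leveled) {
    lref_lane <- lanes[[left_lads[which.min(centers[left_lads])]]]
    rref_lane <- lanes[[right_lads[which.max(centers[right_lads])]]]
    lrow <- .top_band_row(extract_profile(gel, lref_lane))
    rrow <- .top_band_row(extract_profile(gel, rref_lane))
    gel <- level_gel(gel, c(lrow, lref_lane$center_col),
                     c(rrow, rref_lane$center_col))
  }
  if (!gel$background_subtracted) {
    gel <- subtract_background(gel, background_radius)
  }

  profiles <- lapply(lanes, function(l) extract_profile(gel, l))
  names(profiles) <- vapply(lanes, function(l) l$label, character(1))

  call_ladder <- function(idx, model = NULL) {
    tryCatch(find_band_peaks(profiles[[idx]], ladder, model = model,
                             min_prominence_frac = min_prominence_frac),
             gelquant_ladder_call_error = function(e) NULL)
  }
  pick_side <- function(cands) {
    calls <- lapply(cands, call_ladder)
    n_assigned <- vapply(calls, function(p)
      if (is.null(p)) 0L else sum(!is.na(p$assigned_size)), integer(1))
    if (all(n_assigned == 0L)) {
      .stop_gelquant("no usable ladder lane (band calls failed)",
                     "gelquant_ladder_call_error")
    }
    best <- which(n_assigned == max(n_assigned))
    if (length(best) > 1L) {
      bright <- vapply(cands[best], function(i) sum(profiles[[i]]$values),
                       numeric(1))
      best <- best[which.max(bright)]
    }
    list(idx = cands[best[1L]], peaks = calls[[best[1L]]])
  }
  left <- pick_side(left_lads)
  right <- pick_side(right_lads)

  ok <- !is.na(left$peaks$assigned_size)
  model <- fit_migration_model(left$peaks$row[ok],
                               left$peaks$assigned_size[ok])
  # second pass on the right ladder with model guidance
  right$peaks <- call_ladder(right$idx, model = model) %||% right$peaks

  tspec <- threshold_spec(
    ladder, band_size,
    left_apex_row = apex_of_threshold_band(left$peaks, band_size),
    right_apex_row = apex_of_threshold_band(right$peaks, band_size),
    left_lane_col = centers[left$idx],
    right_lane_col = centers[right$idx])

  quant <- lapply(samples, function(i) {
    lane <- lanes[[i]]
    warn <- character()
    if (gel$saturation_fraction > 0.01) warn <- c(warn, "saturation")
    pr <- close_profile(profiles[[i]], tol_frac = closure_tol)
    if (pr$closure_applied) warn <- c(warn, "closure-applied")
    if (!is.null(masks) && lane$label %in% names(masks)) {
      for (seg in masks[[lane$label]]) {
        pr <- mask_artifact(pr, seg[1L], seg[2L])
      }
    }
    profiles[[i]] <<- pr
    t_row <- threshold_row_for_lane(tspec, lane$center_col)
    areas <- integrate_regions(pr, t_row)
    pct <- if (sum(areas) < 1e-6 * length(pr$values)) {
      warn <- c(warn, "empty-lane")
      NA_real_
    } else {
      percent_above_threshold(areas[["area_above"]], areas[["area_below"]])
    }
    data.frame(label = lane$label, threshold_row = t_row,
               area_above = areas[["area_above"]],
               area_below = areas[["area_below"]],
               percent_above = pct,
               warnings = paste(warn, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  quant <- do.call(rbind, quant)
  rownames(quant) <- NULL

  structure(list(
    quantification = quant,
    threshold = tspec,
    model = model,
    ladder_peaks = list(left = left$peaks, right = right$peaks),
    profiles = profiles,
    lanes = lanes,
    gel_meta = list(source = gel$source, bit_depth = gel$bit_depth,
                    rotation_applied = gel$rotation_applied,
                    saturation_fraction = gel$saturation_fraction),
    params = list(ladder = ladder$name, band_size = band_size,
                  background_radius = background_radius,
                  closure_tol = closure_tol,
                  min_prominence_frac = min_prominence_frac)
  ), class = "gel_score")
}

#' @export
print.gel_score <- function(x, ...) {
  cat(sprintf("<gel_score> threshold %s bp (%s ladder)\n",
              format(x$threshold$band_size, big.mark = ","),
              x$threshold$ladder_name))
  q <- x$quantification
  q$percent_above <- round(q$percent_above, 1)
  print(q[, c("label", "percent_above", "warnings")], row.names = FALSE)
  invisible(x)
}
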
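# Lane boxes and per-lane intensity profiles: the vertical-box workflow of
# manual gel densitometry, with an optional automatic lane finder.

#' Define a lane box
#'
#' A lane box is the vertical rectangle over one lane from which the 1-D
#' intensity profile is read. All boxes in one analysis share the same
#' vertical extent (`row_top`, `row_bottom`), starting below the wells and
#' reaching past the smallest fragments.
#'
#' @param gel A [gel_image()] (used for bounds checking).
#' @param center_col Lane centre column, pixels.
#' @param width Box width in pixels (>= 3).
#' @param row_top,row_bottom Shared vertical extent, pixels.
#' @param role `"ladder"` or `"sample"`.
#' @param label Lane label used in outputs.
#' @return An object of class `lane_box`.
#' @export
define_lane <- function(gel, center_col, width, row_top, row_bottom,
                        role = c("sample", "ladder"), label = "") {
  role <- match.arg(role)
  width <- as.integer(round(width))
  if (width < 3L) {
    .stop_gelquant("lane width must be >= 3 px", "gelquant_geometry_error")
  }
  if (row_top >= row_bottom) {
    .stop_gelquant("row_top must be less than row_bottom",
                   "gelquant_geometry_error")
  }
  cols <- .lane_cols(center_col, width)
  d <- dim(gel$raster)
  if (row_top < 1L || row_bottom > d[1L] || cols[1L] < 1L ||
      cols[length(cols)] > d[2L]) {
    .stop_gelquant("lane box extends outside the image",
                   "gelquant_geometry_error")
  }
  structure(list(center_col = center_col, width = width,
                 row_top = as.integer(row_top),
                 row_bottom = as.integer(row_bottom),
                 role = role, label = label),
            class = "lane_box")
}

#' @noRd
.lane_cols <- function(center_col, width) {
  lo <- round(center_col) - floor((width - 1L) / 2L)
  seq.int(lo, length.out = width)
}

#' @export
print.lane_box <- function(x, ...) {
  cat(sprintf("<lane_box> '%s' (%s): col %g +/- %d px, rows %d-%d\n",
              x$label, x$role, x$center_col, x$width %/% 2L,
              x$row_top, x$row_bottom))
  invisible(x)
}

#' Read a lane layout configuration
#'
#' The layout file (YAML or JSON) gives the shared vertical extent and one
#' entry per lane: `row_top`, `row_bottom`, and `lanes:` a list of
#' `{label, role, center_col, width}`. Columns are in pixels.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` layout file.
#' @param gel A [gel_image()] used to validate the boxes.
#' @return List of [define_lane()] boxes.
#' @export
read_lane_layout <- function(path, gel) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(cfg$lanes, function(l) {
    define_lane(gel, l$center_col, l$width %||% cfg$width,
                cfg$row_top, cfg$row_bottom, role = l$role,
                label = l$label %||% "")
  })
}

#' Automatically propose lane boxes
#'
#' Convenience detector: the column-wise mean intensity of the preprocessed
#' gel is smoothed and split into lane segments at the inter-lane gaps
#' (prominent dips and low-signal stretches); each segment's intensity
#' centroid becomes a lane centre. Works for well-separated and abutting
#' lanes alike; segments closer than half the median lane spacing merge
#' into one. Manual layouts remain authoritative for quantitative work.
#'
#' @param gel An inverted (ideally background-subtracted) [gel_image()].
#' @param expected_count Optional expected number of lanes; a mismatch
#'   produces a warning, not an error.
#' @param row_top,row_bottom Vertical extent given to the proposed boxes;
#'   defaults to the full image.
#' @param width_frac Box width as a fraction of the median inter-lane
#'   spacing (default 0.8).
#' @return List of [define_lane()] boxes (role `"sample"`, labels
#'   `lane01`, `lane02`, ...).
#' @export
auto_detect_lanes <- function(gel, expected_count = NULL, row_top = 1L,
                              row_bottom = nrow(gel$raster),
                              width_frac = 0.8) {
  profile <- colMeans(gel$raster[row_top:row_bottom, , drop = FALSE])
  sm <- .running_mean(profile, 2L)
  n <- length(sm)
  mx <- max(sm)
  if (mx <= 1e-6) {
    .stop_gelquant("no lanes detected (blank image)",
                   "gelquant_detection_error")
  }
  # boundaries: prominent dips between lanes plus low-signal stretches
  dips <- .find_peaks(mx - sm, min_prominence = 0.05 * mx)$index
  is_boundary <- logical(n)
  is_boundary[c(1L, n, dips)] <- TRUE
  is_boundary[sm < 0.1 * mx] <- TRUE
  runs <- rle(is_boundary)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  segs <- cbind(run_start[!runs$values], run_end[!runs$values])
  centers <- numeric(0)
  for (i in seq_len(nrow(segs))) {
    idx <- segs[i, 1L]:segs[i, 2L]
    if (max(sm[idx]) < 0.3 * mx) next
    wgt <- sm[idx] - min(sm[idx])
    if (sum(wgt) <= 0) next
    centers <- c(centers, round(sum(idx * wgt) / sum(wgt)))
  }
  if (!length(centers)) {
    .stop_gelquant("no lanes detected", "gelquant_detection_error")
  }
  centers <- sort(centers)
  # merge centres closer than half the median spacing
  if (length(centers) > 2L) {
    min_sep <- stats::median(diff(centers)) / 2
    merged <- centers[1L]
    for (c0 in centers[-1L]) {
      if (c0 - merged[length(merged)] < min_sep) {
        merged[length(merged)] <- round((merged[length(merged)] + c0) / 2)
      } else merged <- c(merged, c0)
    }
    centers <- merged
  }
  if (!is.null(expected_count) && length(centers) != expected_count) {
    warning(sprintf("auto_detect_lanes: found %d lanes, expected %d",
                    length(centers), expected_count))
  }
  spacing <- if (length(centers) > 1L) stats::median(diff(centers))
             else ncol(gel$raster) / 4
  w <- max(3L, round(width_frac * spacing))
  # shrink boxes that would overhang the image edges
  lapply(seq_along(centers), function(i) {
    c0 <- centers[i]
    wi <- min(w, 2L * (c0 - 1L) + 1L, 2L * (ncol(gel$raster) - c0) + 1L)
    define_lane(gel, c0, wi, row_top, row_bottom, role = "sample",
                label = sprintf("lane%02d", i))
  })
}

#' Extract a lane intensity profile
#'
#' The profile is the mean intensity across the box width at each row of
#' the shared vertical extent (the manual workflow sums columns; the mean
#' differs only by the constant box width, leaving all area ratios
#' unchanged, and is invariant to box width over laterally uniform lanes).
#'
#' On a background-subtracted gel the mean is taken over the signed
#' residual and clamped at zero afterwards, so zero-mean sensor noise in
#' empty stretches does not rectify into spurious positive area.
#'
#' @param gel A [gel_image()].
#' @param lane A [define_lane()] box.
#' @return An object of class `lane_profile`: list with `values` (one per
#'   row), `rows` (absolute row indices), `lane`, `closed`,
#'   `mask_segments`.
#' @export
extract_profile <- function(gel, lane) {
  cols <- .lane_cols(lane$center_col, lane$width)
  rows <- lane$row_top:lane$row_bottom
  src <- gel$residual %||% gel$raster
  vals <- pmax(rowMeans(src[rows, cols, drop = FALSE]), 0)
  structure(list(values = vals, rows = rows, lane = lane,
                 closed = FALSE, closure_applied = FALSE,
                 mask_segments = list()),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("<lane_profile> '%s' (%s): rows %d-%d, peak %.3f, closed: %s\n",
              x$lane$label, x$lane$role, x$rows[1L],
              x$rows[length(x$rows)], max(x$values), x$closed))
  if (length(x$mask_segments)) {
    cat(sprintf("  %d artifact mask segment(s)\n", length(x$mask_segments)))
  }
  invisible(x)
}
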
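# GGBN-standard metadata records, tabular/JSON outputs and audit plots.
# Field names follow the GGBN Gel Image Vocabulary verbatim:
# "DNAThreshold" and "percentAboveThreshold".

#' Build a GGBN gel-image record for one lane
#'
#' @param q One row of a [score_gel()] quantification data frame (a
#'   one-row data frame or a list with the same fields).
#' @param spec The [threshold_spec()] used for scoring.
#' @param provenance Named list of method metadata; recognised entries:
#'   `image_id`, `row_top`, `row_bottom`, `box_width`,
#'   `background_radius`. Anything else is carried through.
#' @return An object of class `ggbn_record` with fields `DNAThreshold`
#'   (bp), `percentAboveThreshold` (or `NA` for an empty lane),
#'   `ladderName`, `imageID`, `laneLabel`, `areaAbove`, `areaBelow`,
#'   `genomicQuality` (candidate indicator: percent at or above 50),
#'   `method`, `warnings`.
#' @export
make_record <- function(q, spec, provenance = list()) {
  q <- as.list(q)
  pct <- q$percent_above
  if (!is.na(pct) && (pct < 0 || pct > 100)) {
    .stop_gelquant("percent above threshold outside [0, 100]",
                   "gelquant_internal_error")
  }
  warns <- q$warnings %||% ""
  warns <- if (identical(warns, "")) character() else
    strsplit(warns, ";", fixed = TRUE)[[1L]]
  method <- provenance
  method$image_id <- NULL
  method$softwareVersion <- paste0(
    "gelquant ", as.character(utils::packageVersion("gelquant")))
  structure(list(
    DNAThreshold = spec$band_size,
    percentAboveThreshold = pct,
    ladderName = spec$ladder_name,
    imageID = provenance$image_id %||% "unknown",
    laneLabel = q$label,
    areaAbove = q$area_above,
    areaBelow = q$area_below,
    genomicQuality = if (is.na(pct)) NA else pct >= 50,
    method = method,
    warnings = warns
  ), class = "ggbn_record")
}

#' @export
print.ggbn_record <- function(x, ...) {
  cat(sprintf("<ggbn_record> %s @ %s: DNAThreshold %s bp, percentAboveThreshold %s\n",
              x$imageID, x$laneLabel,
              format(x$DNAThreshold, big.mark = ","),
              if (is.na(x$percentAboveThreshold)) "NA"
              else sprintf("%.1f", x$percentAboveThreshold)))
  invisible(x)
}

#' Build GGBN records for every scored lane
#'
#' @param score A [score_gel()] result.
#' @param image_id Identifier of the source image (defaults to the gel's
#'   source path).
#' @return List of [make_record()] objects.
#' @export
make_records <- function(score, image_id = NULL) {
  prov <- list(
    image_id = image_id %||% score$gel_meta$source,
    row_top = score$lanes[[1L]]$row_top,
    row_bottom = score$lanes[[1L]]$row_bottom,
    box_width = score$lanes[[1L]]$width,
    background_radius = score$params$background_radius)
  lapply(seq_len(nrow(score$quantification)), function(i) {
    make_record(score$quantification[i, ], score$threshold, prov)
  })
}

.schema_path <- function() {
  system.file("schema", "ggbn-record.schema.json", package = "gelquant",
              mustWork = TRUE)
}

#' Validate a record against the shipped schema
#'
#' Checks required fields, types and numeric ranges against the JSON
#' schema document shipped with the package.
#'
#' @param record A [make_record()] object (or equivalent list).
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_record <- function(record) {
  schema <- jsonlite::read_json(.schema_path(), simplifyVector = FALSE)
  for (f in unlist(schema$required)) {
    if (!f %in% names(record)) {
      .stop_gelquant(sprintf("record missing required field '%s'", f),
                     "gelquant_schema_error")
    }
  }
  for (f in names(schema$properties)) {
    if (!f %in% names(record)) next
    val <- record[[f]]
    prop <- schema$properties[[f]]
    types <- unlist(prop$type)
    if (is.null(val) || (length(val) == 1L && is.na(val))) {
      if (!"null" %in% types) {
        .stop_gelquant(sprintf("field '%s' may not be null", f),
                       "gelquant_schema_error")
      }
      next
    }
    ok <- any(vapply(types, function(tp) switch(tp,
      number = is.numeric(val),
      string = is.character(val),
      boolean = is.logical(val),
      array = is.vector(val) || is.list(val),
      object = is.list(val),
      null = FALSE, FALSE), logical(1)))
    if (!ok) {
      .stop_gelquant(sprintf("field '%s' has wrong type", f),
                     "gelquant_schema_error")
    }
    if (is.numeric(val)) {
      if (!is.null(prop$minimum) && any(val < prop$minimum, na.rm = TRUE)) {
        .stop_gelquant(sprintf("field '%s' below minimum %s", f,
                               prop$minimum), "gelquant_schema_error")
      }
      if (!is.null(prop$maximum) && any(val > prop$maximum, na.rm = TRUE)) {
        .stop_gelquant(sprintf("field '%s' above maximum %s", f,
                               prop$maximum), "gelquant_schema_error")
      }
    }
  }
  invisible(TRUE)
}

#' @noRd
.records_to_frame <- function(records) {
  rows <- lapply(records, function(r) {
    data.frame(
      laneLabel = r$laneLabel,
      imageID = r$imageID,
      ladderName = r$ladderName,
      DNAThreshold = r$DNAThreshold,
      areaAbove = r$areaAbove,
      areaBelow = r$areaBelow,
      percentAboveThreshold = r$percentAboveThreshold,
      genomicQuality = r$genomicQuality,
      warnings = paste(r$warnings, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write GGBN records to CSV and/or JSON
#'
#' Field order is fixed, so identical inputs give byte-identical files.
#' CSV percentages are reported to one decimal place; the JSON carries
#' full precision and validates against the shipped schema.
#'
#' @param records List of [make_record()] objects.
#' @param csv,json Output paths (either may be `NULL`).
#' @return Invisible named list of the paths written.
#' @export
write_outputs <- function(records, csv = NULL, json = NULL) {
  if (!length(records)) {
    .stop_gelquant("no records to write", "gelquant_io_error")
  }
  lapply(records, validate_record)
  written <- list()
  if (!is.null(csv)) {
    df <- .records_to_frame(records)
    df$percentAboveThreshold <- round(df$percentAboveThreshold, 1)
    ok <- tryCatch({
      utils::write.csv(df, csv, row.names = FALSE, quote = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) .stop_gelquant(sprintf("cannot write '%s'", csv),
                            "gelquant_io_error")
    written$csv <- csv
  }
  if (!is.null(json)) {
    payload <- lapply(records, function(r) {
      r <- unclass(r)
      r$percentAboveThreshold <-
        if (is.na(r$percentAboveThreshold)) NULL else r$percentAboveThreshold
      r$genomicQuality <- if (is.na(r$genomicQuality)) NULL else r$genomicQuality
      r
    })
    ok <- tryCatch({
      jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) .stop_gelquant(sprintf("cannot write '%s'", json),
                            "gelquant_io_error")
    written$json <- json
  }
  invisible(written)
}

#' Read GGBN records back from JSON
#'
#' @param path A JSON file written by [write_outputs()].
#' @return List of `ggbn_record` objects.
#' @export
read_records <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    r$percentAboveThreshold <- r$percentAboveThreshold %||% NA_real_
    r$genomicQuality <- r$genomicQuality %||% NA
    r$warnings <- as.character(unlist(r$warnings))
    r$percentAboveThreshold <- as.numeric(r$percentAboveThreshold)
    structure(r, class = "ggbn_record")
  })
}

#' Render an annotated audit plot of a scored gel
#'
#' Left panel: the processed gel image with the lane boxes. Right panel:
#' stacked lane intensity profiles with the interpolated DNA-threshold
#' line through the ladder apexes, shading of the above-threshold region,
#' and masked artifact segments drawn distinctly.
#'
#' @param score A [score_gel()] result.
#' @param gel The [gel_image()] that was scored (any preprocessing state;
#'   used only as the backdrop).
#' @param path Output PNG path.
#' @return Invisible list with `path` and `threshold_endpoints` (the apex
#'   rows anchoring the threshold line). Plot failures warn rather than
#'   abort.
#' @export
render_audit_plot <- function(score, gel, path) {
  endpoints <- data.frame(
    side = c("left", "right"),
    col = c(score$threshold$left_lane_col, score$threshold$right_lane_col),
    row = c(score$threshold$left_apex_row, score$threshold$right_apex_row))
  ok <- tryCatch({
    grDevices::png(path, width = 1200, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))

    m <- gel$raster
    graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                    z = t(m)[, rev(seq_len(nrow(m)))],
                    col = grDevices::gray.colors(256, 0, 1),
                    xlab = "column (px)", ylab = "row (px)",
                    main = "gel image and lane boxes", yaxt = "n",
                    useRaster = TRUE)
    at <- pretty(c(1, nrow(m)))
    graphics::axis(2, at = nrow(m) - at + 1, labels = at)
    flip <- function(r) nrow(m) - r + 1
    for (l in score$lanes) {
      cols <- range(.lane_cols(l$center_col, l$width))
      graphics::rect(cols[1L], flip(l$row_bottom), cols[2L],
                     flip(l$row_top),
                     border = if (l$role == "ladder") "orange" else "yellow",
                     lwd = 1.5)
    }
    graphics::segments(endpoints$col[1L], flip(endpoints$row[1L]),
                       endpoints$col[2L], flip(endpoints$row[2L]),
                       col = "red", lwd = 2)

    prof <- score$profiles
    step <- max(vapply(prof, function(p) max(p$values), numeric(1))) * 1.2
    graphics::plot(NULL, xlim = range(prof[[1L]]$rows),
                   ylim = c(0, step * length(prof)),
                   xlab = "migration distance (row, px)",
                   ylab = "intensity (stacked)",
                   main = sprintf("profiles and %s bp threshold",
                                  format(score$threshold$band_size,
                                         big.mark = ",")))
    qdf <- score$quantification
    for (i in seq_along(prof)) {
      pr <- prof[[i]]
      off <- step * (length(prof) - i)
      graphics::lines(pr$rows, pr$values + off, lwd = 1)
      lab <- pr$lane$label
      graphics::text(pr$rows[1L], off + step * 0.55, lab, adj = 0, cex = 0.8)
      hit <- which(qdf$label == lab)
      if (length(hit)) {
        t_row <- qdf$threshold_row[hit[1L]]
        above <- pr$rows <= t_row
        graphics::polygon(c(pr$rows[above], rev(pr$rows[above])),
                          c(pr$values[above] + off,
                            rep(off, sum(above))),
                          col = grDevices::adjustcolor("steelblue", 0.3),
                          border = NA)
        graphics::segments(t_row, off, t_row, off + step * 0.9,
                           col = "red", lwd = 1.5)
      }
      for (seg in pr$mask_segments) {
        idx <- pr$rows >= seg[1L] & pr$rows <= seg[2L]
        graphics::lines(pr$rows[idx], pr$values[idx] + off,
                        col = "magenta", lwd = 2, lty = 2)
      }
    }
    TRUE
  }, error = function(e) {
    warning("audit plot failed: ", conditionMessage(e))
    FALSE
  })
  invisible(list(path = if (ok) path else NULL,
                 threshold_endpoints = endpoints))
}
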
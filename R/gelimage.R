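# Gel image container and preprocessing: load, invert, level, subtract
# background. Convention: the raster is a numeric matrix in [0, 1] with
# row 1 at the wells; migration distance increases with row index.

#' Construct a gel image object
#'
#' @param raster Numeric matrix of intensities in `[0, 1]`; rows follow the
#'   migration axis (wells at row 1), columns the lateral axis.
#' @param bit_depth Bit depth of the source data (8 or 16).
#' @param inverted Has the image been colour-inverted (DNA bright)?
#' @param leveled Has the image been rotated level?
#' @param background_subtracted Has the smooth background been removed?
#' @param rotation_applied Cumulative rotation applied, degrees.
#' @param saturation_fraction Fraction of source pixels at the source
#'   maximum value.
#' @param source Provenance string (file path or `"synthetic"`).
#' @return An object of class `gel_image`.
#' @export
gel_image <- function(raster, bit_depth = 16L, inverted = FALSE,
                      leveled = FALSE, background_subtracted = FALSE,
                      rotation_applied = 0, saturation_fraction = 0,
                      source = "in-memory") {
  if (!is.matrix(raster) || !is.numeric(raster)) {
    .stop_gelquant("raster must be a numeric matrix", "gelquant_image_error")
  }
  if (anyNA(raster) || min(raster) < 0 || max(raster) > 1) {
    .stop_gelquant("raster intensities must lie in [0, 1]",
                   "gelquant_image_error")
  }
  if (background_subtracted && !inverted) {
    .stop_gelquant("background subtraction requires an inverted image",
                   "gelquant_image_error")
  }
  structure(list(raster = raster, bit_depth = as.integer(bit_depth),
                 inverted = inverted, leveled = leveled,
                 background_subtracted = background_subtracted,
                 rotation_applied = rotation_applied,
                 saturation_fraction = saturation_fraction,
                 source = source),
            class = "gel_image")
}

#' @export
print.gel_image <- function(x, ...) {
  cat(sprintf("<gel_image> %d x %d px, %d-bit source (%s)\n",
              nrow(x$raster), ncol(x$raster), x$bit_depth, x$source))
  cat(sprintf("  inverted: %s | leveled: %s (%.3f deg) | background subtracted: %s\n",
              x$inverted, x$leveled, x$rotation_applied,
              x$background_subtracted))
  cat(sprintf("  saturation fraction: %.2g\n", x$saturation_fraction))
  invisible(x)
}

#' @export
dim.gel_image <- function(x) dim(x$raster)

.png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  as.integer(hdr[25L])
}

#' Load a gel image from TIFF or PNG
#'
#' Accepts 8- or 16-bit grayscale images (RGB is converted to Rec. 709
#' luminance). Intensities are normalised to `[0, 1]` by the bit-depth
#' maximum and the fraction of saturated source pixels is recorded; the
#' image is assumed photographed with the wells at the top.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return A [gel_image()].
#' @export
load_gel <- function(path) {
  if (!file.exists(path)) {
    .stop_gelquant(sprintf("cannot read image '%s'", path), "gelquant_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e)
                      .stop_gelquant(sprintf("unreadable TIFF '%s': %s", path,
                                             conditionMessage(e)),
                                     "gelquant_io_error"))
    bits <- attr(img, "bits.per.sample") %||% 8L
  } else if (ext == "png") {
    img <- tryCatch(png::readPNG(path),
                    error = function(e)
                      .stop_gelquant(sprintf("unreadable PNG '%s': %s", path,
                                             conditionMessage(e)),
                                     "gelquant_io_error"))
    bits <- .png_bit_depth(path)
  } else {
    .stop_gelquant(sprintf("unsupported image format '.%s'", ext),
                   "gelquant_io_error")
  }
  if (!bits %in% c(8L, 16L)) {
    .stop_gelquant(sprintf("unsupported bit depth %d", bits),
                   "gelquant_io_error")
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] >= 3L) {
      img <- 0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
    } else {
      img <- img[, , 1L]
    }
  }
  dims <- dim(img)[1:2]
  img <- as.numeric(img)
  dim(img) <- dims
  # readTIFF/readPNG already normalise by the bit-depth maximum, so source
  # saturation corresponds to a value of exactly 1.
  sat <- mean(img >= 1)
  gel_image(pmin(pmax(img, 0), 1), bit_depth = bits,
            saturation_fraction = sat, source = path)
}

#' Write a gel image raster to a 16-bit TIFF
#'
#' Intended for audit copies of processed images.
#'
#' @param gel A [gel_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gel <- function(gel, path) {
  tiff::writeTIFF(gel$raster, path, bits.per.sample = 16L)
  invisible(path)
}

#' Colour-invert a gel image
#'
#' Maps intensity to `1 - intensity` so that DNA (stained bands) is bright
#' and lane density curves are positive. Inversion is explicit: a gel
#' already flagged inverted cannot be inverted again, and a heuristic
#' warning fires if the image already appears dark-background.
#'
#' @param gel A [gel_image()].
#' @return The inverted [gel_image()].
#' @export
invert_gel <- function(gel) {
  if (gel$inverted) {
    .stop_gelquant("image is already inverted", "gelquant_state_error")
  }
  m <- gel$raster
  if (stats::median(m) < mean(m)) {
    warning("image looks dark-background already; inverting anyway")
  }
  gel$raster <- 1 - m
  gel$inverted <- TRUE
  gel
}

# Rotate a matrix about its centre by `degrees` (bilinear), preserving size.
#' @noRd
.rotate_raster <- function(m, degrees, fill) {
  EBImage::rotate(m, degrees, filter = "bilinear", output.dim = dim(m),
                  bg.col = fill)
}

#' Level a gel image with respect to two reference points
#'
#' Rotates the image about its centre so that the two reference points (the
#' top-ladder-band centres in the left and right ladder lanes) come to lie
#' on one row, mirroring the make-level step of manual gel scoring.
#' Intensities are resampled bilinearly and re-clamped to `[0, 1]`. When the
#' references are already level the raster is returned bit-identical.
#'
#' @param gel A [gel_image()].
#' @param left_ref,right_ref Numeric `(row, col)` pairs; distinct columns.
#' @return The leveled [gel_image()] with `rotation_applied` updated.
#' @export
level_gel <- function(gel, left_ref, right_ref) {
  if (left_ref[2L] == right_ref[2L]) {
    .stop_gelquant("reference points must have distinct columns",
                   "gelquant_geometry_error")
  }
  dr <- right_ref[1L] - left_ref[1L]
  dc <- right_ref[2L] - left_ref[2L]
  angle <- atan2(dr, dc) * 180 / pi
  if (abs(angle) > 1e-12) {
    fill <- stats::median(gel$raster)
    gel$raster <- pmin(pmax(.rotate_raster(gel$raster, angle, fill), 0), 1)
    if (!is.null(gel$residual)) {
      gel$residual <- .rotate_raster(gel$residual, angle, 0)
    }
  }
  gel$rotation_applied <- gel$rotation_applied + angle
  gel$leveled <- TRUE
  gel
}

#' Subtract the smooth gel background
#'
#' Estimates the smooth continuous background by greyscale morphological
#' opening with a disc structuring element (the rolling-ball approach of
#' densitometry software) and subtracts it, clamping at zero. The disc
#' radius must exceed the largest band half-width so that bands are not
#' absorbed into the background.
#'
#' The opening is computed on a denoised copy (median filter then a light
#' Gaussian blur): a raw greyscale minimum over thousands of noisy pixels
#' is biased low by several noise SDs, which would leave a spurious
#' pedestal under every lane. The median stage preserves the exact zeros
#' of an already-subtracted image, keeping repeated subtraction a
#' near-no-op.
#'
#' Because the background under a lane is never directly observed (the
#' lane occupies its full height), the opening can carry a small
#' slope-coupled bump there; a final wide smoothing of the estimate
#' averages it with the accurately estimated inter-lane gaps.
#'
#' The raster is clamped to `[0, 1]` after subtraction, but the signed
#' residual is retained alongside it: averaging the residual across a lane
#' box before clamping (see [extract_profile()]) avoids the positive bias
#' that per-pixel clamping of noise would add to empty profile regions.
#'
#' The estimate is then smoothed at two scales,
#' `G_s(bg) + G_c(bg - G_s(bg))` with sigmas `estimate_sigma` and
#' `estimate_sigma_coarse`: the first stage suppresses the narrow
#' slope-coupled bumps, while the second adds back the large-scale field
#' the first stage attenuated, so genuinely curved backgrounds (vignettes)
#' are preserved and repeated subtraction stays a near-no-op.
#'
#' @param gel An inverted [gel_image()].
#' @param ball_radius Structuring-element radius in pixels (default 50).
#' @param denoise_median,denoise_sigma Median-filter radius and Gaussian
#'   sigma used to denoise the copy on which the background is estimated.
#' @param estimate_sigma,estimate_sigma_coarse Sigmas of the two-scale
#'   smoothing of the background estimate.
#' @return The background-subtracted [gel_image()], with the signed
#'   pre-clamp residual in `$residual`.
#' @export
subtract_background <- function(gel, ball_radius = 50, denoise_median = 3,
                                denoise_sigma = 6, estimate_sigma = 60,
                                estimate_sigma_coarse = 75) {
  if (ball_radius <= 0) {
    .stop_gelquant("ball_radius must be positive", "gelquant_parameter_error")
  }
  if (!gel$inverted) {
    .stop_gelquant("subtract_background requires an inverted image",
                   "gelquant_state_error")
  }
  sm <- gel$raster
  if (denoise_median > 0) sm <- EBImage::medianFilter(sm, denoise_median)
  sm <- .gblur_safe(sm, denoise_sigma)
  brush <- EBImage::makeBrush(2L * round(ball_radius) + 1L, shape = "disc")
  bg <- EBImage::opening(sm, brush)
  if (estimate_sigma > 0) {
    s1 <- .gblur_safe(bg, estimate_sigma)
    bg <- s1 + .gblur_safe(bg - s1, estimate_sigma_coarse)
  }
  gel$residual <- gel$raster - bg
  gel$raster <- pmin(pmax(gel$residual, 0), 1)
  gel$background_subtracted <- TRUE
  gel
}

# gblur with the kernel capped to fit inside the image (EBImage refuses
# filters larger than the image); tiny effective sigmas are a no-op.
#' @noRd
.gblur_safe <- function(x, sigma) {
  s <- min(sigma, (min(dim(x)) - 1) / 6.5)
  if (s < 0.5) return(x)
  EBImage::gblur(x, s)
}
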
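# DNA ladder catalogue and size <-> migration-distance calibration.

#' Construct a ladder definition
#'
#' A ladder definition names a molecular-weight marker and lists its
#' fragment sizes in base pairs, largest first. A subset of the bands may be
#' designated as usable DNA-threshold standards (the "X" in
#' greater-than-X-kb).
#'
#' @param name Ladder identifier (e.g. `"hindiii"`).
#' @param band_sizes Numeric vector of fragment lengths in bp, strictly
#'   decreasing, all positive.
#' @param threshold_candidates Subset of `band_sizes` recommended as
#'   threshold standards. Defaults to all bands.
#' @return An object of class `ladder_definition`.
#' @export
ladder_definition <- function(name, band_sizes,
                              threshold_candidates = band_sizes) {
  band_sizes <- as.numeric(band_sizes)
  if (any(band_sizes <= 0) || any(diff(band_sizes) >= 0)) {
    .stop_gelquant("band_sizes must be strictly decreasing and positive",
                   "gelquant_ladder_error")
  }
  threshold_candidates <- as.numeric(threshold_candidates)
  if (!all(threshold_candidates %in% band_sizes)) {
    .stop_gelquant("every threshold candidate must be one of band_sizes",
                   "gelquant_ladder_error")
  }
  structure(list(name = name, band_sizes = band_sizes,
                 threshold_candidates = threshold_candidates),
            class = "ladder_definition")
}

#' @export
print.ladder_definition <- function(x, ...) {
  cat("<ladder_definition> ", x$name, "\n", sep = "")
  cat("  bands (bp):", paste(format(x$band_sizes, big.mark = ",",
                                    trim = TRUE), collapse = ", "), "\n")
  cat("  threshold candidates:",
      paste(format(x$threshold_candidates, big.mark = ",", trim = TRUE),
            collapse = ", "), "\n")
  invisible(x)
}

.ladder_catalog_path <- function() {
  system.file("extdata", "ladders.json", package = "gelquant", mustWork = TRUE)
}

.ladder_catalog <- function() {
  cat_raw <- jsonlite::read_json(.ladder_catalog_path(), simplifyVector = FALSE)
  cat_raw <- lapply(cat_raw, function(l) {
    l$band_sizes_bp <- as.numeric(unlist(l$band_sizes_bp))
    if (!is.null(l$threshold_candidates_bp)) {
      l$threshold_candidates_bp <- as.numeric(unlist(l$threshold_candidates_bp))
    }
    l
  })
  stats::setNames(cat_raw, vapply(cat_raw, function(l) l$name, character(1)))
}

#' List the built-in ladder catalogue
#'
#' @return Character vector of ladder names known to [builtin_ladder()].
#' @export
list_ladders <- function() names(.ladder_catalog())

#' Retrieve a built-in ladder definition
#'
#' The catalogue ships with the classic lambda-phage HindIII digest
#' (`"hindiii"`), whose visible bands are 23,130; 9,416; 6,557; 4,361;
#' 2,322; 2,027 and 564 bp. Its six largest bands are the conventional
#' threshold candidates, with 9,416 bp (~"9 kb") the usual working standard.
#'
#' @param name Ladder identifier, case-insensitive.
#' @return A [ladder_definition()].
#' @export
#' @examples
#' builtin_ladder("hindiii")
builtin_ladder <- function(name) {
  cat_ <- .ladder_catalog()
  key <- tolower(name)
  if (!key %in% names(cat_)) {
    .stop_gelquant(sprintf("unknown ladder '%s'; available: %s", name,
                           paste(names(cat_), collapse = ", ")),
                   "gelquant_catalog_error")
  }
  entry <- cat_[[key]]
  ladder_definition(entry$name, entry$band_sizes_bp,
                    entry$threshold_candidates_bp %||% entry$band_sizes_bp)
}

#' Read a user ladder from a JSON file
#'
#' The file uses the same format as the shipped catalogue entry:
#' `{"name": ..., "band_sizes_bp": [...], "threshold_candidates_bp": [...]}`.
#'
#' @param path Path to a JSON ladder file.
#' @return A [ladder_definition()].
#' @export
read_ladder <- function(path) {
  entry <- jsonlite::read_json(path, simplifyVector = FALSE)
  ladder_definition(entry$name, as.numeric(unlist(entry$band_sizes_bp)),
                    as.numeric(unlist(entry$threshold_candidates_bp %||%
                                        entry$band_sizes_bp)))
}

#' Calibrate migration distance against fragment size
#'
#' Fits the first-order agarose migration model: distance is linear in
#' log10(fragment size), with distance strictly decreasing in size. The fit
#' is ordinary least squares over the supplied (position, size) pairs;
#' per-band residuals are retained so curvature can be inspected.
#'
#' @param band_positions Migration distances of matched ladder bands, in
#'   pixel rows from the wells.
#' @param band_sizes Fragment sizes in bp matching `band_positions`.
#' @return An object of class `migration_model` with elements
#'   `coefficients` (intercept `a`, slope `b` of `distance = a + b log10(size)`),
#'   `residuals` (named per band, in pixels), and `size_range` (bp).
#' @export
fit_migration_model <- function(band_positions, band_sizes) {
  if (length(band_positions) != length(band_sizes) ||
      length(band_sizes) < 2L) {
    .stop_gelquant("need >= 2 matched (position, size) pairs",
                   "gelquant_calibration_error")
  }
  ord <- order(band_sizes, decreasing = TRUE)
  pos <- band_positions[ord]
  siz <- band_sizes[ord]
  if (any(siz <= 0)) {
    .stop_gelquant("band sizes must be positive", "gelquant_calibration_error")
  }
  if (any(diff(pos) <= 0)) {
    .stop_gelquant(
      "positions must strictly increase as sizes decrease (non-monotone pairs)",
      "gelquant_calibration_error")
  }
  fit <- stats::lm.fit(cbind(1, log10(siz)), pos)
  coefs <- stats::setNames(fit$coefficients, c("a", "b"))
  structure(list(
    coefficients = coefs,
    residuals = stats::setNames(as.numeric(fit$residuals), siz),
    size_range = range(siz),
    bands_used = siz
  ), class = "migration_model")
}

#' @export
print.migration_model <- function(x, ...) {
  cat("<migration_model> distance = a + b*log10(size)\n")
  cat(sprintf("  a = %.4g, b = %.4g; calibrated %s-%s bp (%d bands)\n",
              x$coefficients["a"], x$coefficients["b"],
              format(x$size_range[1], big.mark = ","),
              format(x$size_range[2], big.mark = ","),
              length(x$bands_used)))
  cat(sprintf("  residual RMS: %.3g px\n", sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Expected migration distance of a fragment size
#'
#' @param model A [fit_migration_model()] result.
#' @param size Fragment size(s) in bp.
#' @param warn_extrapolation Warn when `size` falls outside the calibrated
#'   range (extrapolation is performed, never refused silently).
#' @return Distances in pixel rows, with attribute `extrapolated` (logical
#'   per element).
#' @export
position_of_size <- function(model, size, warn_extrapolation = TRUE) {
  if (any(size <= 0)) {
    .stop_gelquant("fragment size must be positive", "gelquant_domain_error")
  }
  extra <- size < model$size_range[1] | size > model$size_range[2]
  if (warn_extrapolation && any(extra)) {
    warning("position_of_size: extrapolating outside the calibrated range")
  }
  d <- model$coefficients["a"] + model$coefficients["b"] * log10(size)
  structure(unname(d), extrapolated = extra)
}

#' Fragment size at a migration distance
#'
#' Exact inverse of [position_of_size()] under the log-linear model.
#'
#' @param model A [fit_migration_model()] result.
#' @param distance Migration distance(s) in pixel rows.
#' @return Sizes in bp, with attribute `extrapolated` (logical per element).
#' @export
size_at_position <- function(model, distance) {
  a <- model$coefficients["a"]
  b <- model$coefficients["b"]
  s <- 10^((distance - a) / b)
  extra <- s < model$size_range[1] | s > model$size_range[2]
  structure(unname(s), extrapolated = extra)
}
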
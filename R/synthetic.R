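# Forward simulator: gel images with known ground truth. Sample lanes carry
# a two-component lognormal fragment-mass distribution (tight high-MW
# "intact" component plus a degraded smear), mapped through a log-linear
# migration model and blurred; ladder lanes carry discrete bands. Smooth
# background, optional shear/rotation distortions, sensor noise and dark
# specks complete the phenomenology of real gel photographs.

#' Specify a synthetic gel
#'
#' Defaults describe a 600 x 480 px, 16-bit gel photograph with two
#' flanking HindIII ladder lanes and four sample lanes whose intact
#' fractions span the quality range (0.9, 0.5, 0.2, 0). Staining signal is
#' proportional to DNA mass, so lane densities are mass-weighted. Fragments
#' beyond the resolvable range co-migrate at the `clamp_top` /
#' `clamp_bottom` rows (limiting mobility and gel front), conserving mass.
#'
#' @param rows,cols Image size in pixels.
#' @param ladder_cols,sample_cols Lane centre columns.
#' @param lane_width Lane width in pixels.
#' @param row_top,row_bottom Vertical extent of the analysis boxes.
#' @param migration Named vector `c(a, b)` of the migration law
#'   `distance = a + b * log10(size)`; `b < 0`.
#' @param ladder Ladder rendered in the flanking lanes.
#' @param w_intact Per-sample mixture weight of the intact component,
#'   recycled to `length(sample_cols)`.
#' @param intact_meanlog,intact_sdlog Intact component, log-bp scale
#'   (default: tight around 40 kb).
#' @param deg_meanlog,deg_sdlog Degraded smear component, log-bp scale
#'   (default: centred on 3 kb, broad).
#' @param lane_mass Total stained mass per sample lane (intensity-pixels).
#' @param band_sigma Band spread (Gaussian sigma) in pixels.
#' @param ladder_amp Peak intensity of the brightest ladder band.
#' @param ladder_rel_floor Minimum relative brightness of faint ladder
#'   bands (mass-proportional amplitudes are floored here so small
#'   fragments stay visible).
#' @param background_base,vignette_amp Smooth background: constant level
#'   plus a centred Gaussian vignette of this amplitude.
#' @param noise_sd Gaussian sensor noise sigma.
#' @param skew_deg Rigid rotation applied to the gel, degrees.
#' @param shear_px Pure vertical shear: linear row offset across the image,
#'   `-shear_px/2` at the left edge to `+shear_px/2` at the right.
#' @param specks List of dark-artifact blobs, each
#'   `list(row, col, amplitude, width)`.
#' @param clamp_top,clamp_bottom Rows absorbing off-scale fragment mass.
#' @param quantize Quantise the rendered image to the 16-bit grid (default
#'   `TRUE`, matching a stored TIFF; disable for exact analytic checks).
#' @param seed Integer; fully determines the rendered image.
#' @return An object of class `synthetic_gel_spec`.
#' @export
synthetic_gel_spec <- function(rows = 600L, cols = 480L,
                               ladder_cols = c(60, 420),
                               sample_cols = c(132, 204, 276, 348),
                               lane_width = 40L,
                               row_top = 60L, row_bottom = 590L,
                               migration = c(a = 1247.8, b = -250),
                               ladder = builtin_ladder("hindiii"),
                               w_intact = c(0.9, 0.5, 0.2, 0),
                               intact_meanlog = log(4e4),
                               intact_sdlog = 0.1,
                               deg_meanlog = log(3000),
                               deg_sdlog = 0.8,
                               lane_mass = 12,
                               band_sigma = 3,
                               ladder_amp = 0.5,
                               ladder_rel_floor = 0.15,
                               background_base = 0.08,
                               vignette_amp = 0.06,
                               noise_sd = 0.01,
                               skew_deg = 0,
                               shear_px = 0,
                               specks = list(),
                               clamp_top = 70L, clamp_bottom = 580L,
                               quantize = TRUE,
                               seed = 1L) {
  ns <- length(sample_cols)
  rec <- function(x) rep_len(x, ns)
  w_intact <- rec(w_intact)
  if (any(w_intact < 0 | w_intact > 1)) {
    .stop_gelquant("w_intact must lie in [0, 1]", "gelquant_spec_error")
  }
  if (migration[["b"]] >= 0) {
    .stop_gelquant("migration slope b must be negative", "gelquant_spec_error")
  }
  if (noise_sd < 0) {
    .stop_gelquant("noise_sd must be >= 0", "gelquant_spec_error")
  }
  band_rows <- migration[["a"]] + migration[["b"]] * log10(ladder$band_sizes)
  if (any(band_rows < 1 | band_rows > rows)) {
    .stop_gelquant("migration law places ladder bands outside the image",
                   "gelquant_spec_error")
  }
  structure(list(
    rows = as.integer(rows), cols = as.integer(cols),
    ladder_cols = ladder_cols, sample_cols = sample_cols,
    lane_width = as.integer(lane_width),
    row_top = as.integer(row_top), row_bottom = as.integer(row_bottom),
    migration = migration, ladder = ladder,
    w_intact = w_intact,
    intact_meanlog = rec(intact_meanlog), intact_sdlog = rec(intact_sdlog),
    deg_meanlog = rec(deg_meanlog), deg_sdlog = rec(deg_sdlog),
    lane_mass = rec(lane_mass),
    band_sigma = band_sigma, ladder_amp = ladder_amp,
    ladder_rel_floor = ladder_rel_floor,
    background_base = background_base, vignette_amp = vignette_amp,
    noise_sd = noise_sd, skew_deg = skew_deg, shear_px = shear_px,
    specks = specks,
    clamp_top = as.integer(clamp_top), clamp_bottom = as.integer(clamp_bottom),
    quantize = isTRUE(quantize),
    seed = as.integer(seed)
  ), class = "synthetic_gel_spec")
}

#' @export
print.synthetic_gel_spec <- function(x, ...) {
  cat(sprintf("<synthetic_gel_spec> %d x %d px, %d sample lane(s), seed %d\n",
              x$rows, x$cols, length(x$sample_cols), x$seed))
  cat(sprintf("  w_intact: %s | noise %.3g | skew %.2f deg | shear %.1f px\n",
              paste(signif(x$w_intact, 3), collapse = ", "),
              x$noise_sd, x$skew_deg, x$shear_px))
  invisible(x)
}

#' True percent of DNA mass above a band size
#'
#' Closed-form tail mass of the sample's lognormal mixture; the simulator's
#' ground truth for percent-above-threshold.
#'
#' @param spec A [synthetic_gel_spec()].
#' @param lane Sample-lane index (1-based, into `sample_cols`).
#' @param band_size Threshold band size in bp.
#' @return Percent in `[0, 100]`.
#' @export
true_percent_above <- function(spec, lane, band_size) {
  if (lane < 1L || lane > length(spec$sample_cols)) {
    .stop_gelquant("lane must index a sample lane", "gelquant_spec_error")
  }
  w <- spec$w_intact[lane]
  100 * (w * stats::plnorm(band_size, spec$intact_meanlog[lane],
                           spec$intact_sdlog[lane], lower.tail = FALSE) +
         (1 - w) * stats::plnorm(band_size, spec$deg_meanlog[lane],
                                 spec$deg_sdlog[lane], lower.tail = FALSE))
}

# Mass per image row for one sample lane: mixture CDF differences across
# row-bin edges, off-scale tails absorbed at the clamp rows, then Gaussian
# band blur. Sums to lane_mass (up to blur leakage at the image ends).
#' @noRd
.sample_lane_profile <- function(spec, lane) {
  a <- spec$migration[["a"]]; b <- spec$migration[["b"]]
  edges <- 0:spec$rows
  size_at <- 10^((edges - a) / b)
  size_at[1L] <- Inf
  size_at[length(size_at)] <- 0
  w <- spec$w_intact[lane]
  cdf <- function(s) {
    w * stats::plnorm(s, spec$intact_meanlog[lane], spec$intact_sdlog[lane]) +
      (1 - w) * stats::plnorm(s, spec$deg_meanlog[lane], spec$deg_sdlog[lane])
  }
  mass <- cdf(size_at[-length(size_at)]) - cdf(size_at[-1L])
  ct <- spec$clamp_top; cb <- spec$clamp_bottom
  mass[ct] <- mass[ct] + sum(mass[seq_len(ct - 1L)])
  mass[seq_len(ct - 1L)] <- 0
  mass[cb] <- mass[cb] + sum(mass[seq.int(cb + 1L, spec$rows)])
  mass[seq.int(cb + 1L, spec$rows)] <- 0
  spec$lane_mass[lane] * .gaussian_blur1d(mass, spec$band_sigma)
}

#' @noRd
.ladder_lane_profile <- function(spec) {
  a <- spec$migration[["a"]]; b <- spec$migration[["b"]]
  sizes <- spec$ladder$band_sizes
  amps <- spec$ladder_amp * pmax(sizes / max(sizes), spec$ladder_rel_floor)
  r <- seq_len(spec$rows)
  v <- numeric(spec$rows)
  for (k in seq_along(sizes)) {
    d <- a + b * log10(sizes[k])
    v <- v + amps[k] * exp(-(r - d)^2 / (2 * spec$band_sigma^2))
  }
  v
}

#' @noRd
.shear_offsets <- function(spec) {
  if (spec$shear_px == 0) return(numeric(spec$cols))
  spec$shear_px * ((seq_len(spec$cols) - 1) / (spec$cols - 1) - 0.5)
}

# Map a pre-rotation point to its post-rotation position (EBImage rotate
# about the image centre, size preserved).
#' @noRd
.rotate_point <- function(r, c, rows, cols, degrees) {
  if (degrees == 0) return(c(r, c))
  phi <- degrees * pi / 180
  cy <- (rows + 1) / 2; cx <- (cols + 1) / 2
  dr <- r - cy; dc <- c - cx
  c(cy + dr * cos(phi) - dc * sin(phi),
    cx + dc * cos(phi) + dr * sin(phi))
}

#' Render a synthetic gel image with ground truth
#'
#' Lane signal, background, shear, rotation, sensor noise and specks are
#' applied in that order; the result is quantised to the 16-bit grid and
#' returned as the raw (dark bands on light background) photograph. The
#' seed fully determines the output.
#'
#' @param spec A [synthetic_gel_spec()].
#' @return An object of class `synthetic_gel`: list with `gel` (a
#'   [gel_image()], uninverted) and `truth` (list: `percent_above` matrix
#'   of sample lanes x ladder bands, `band_rows` matrix of ladder bands x
#'   lanes after distortions, `lane_centers`, `roles`, `labels`).
#' @export
render_gel <- function(spec) {
  .with_seed(spec$seed, {
    rows <- spec$rows; cols <- spec$cols
    img <- matrix(0, rows, cols)
    lad_prof <- .ladder_lane_profile(spec)
    for (c0 in spec$ladder_cols) {
      img[, .lane_cols(c0, spec$lane_width)] <- lad_prof
    }
    for (i in seq_along(spec$sample_cols)) {
      img[, .lane_cols(spec$sample_cols[i], spec$lane_width)] <-
        .sample_lane_profile(spec, i)
    }

    off <- .shear_offsets(spec)
    if (any(off != 0)) {
      rseq <- seq_len(rows)
      for (c0 in seq_len(cols)) {
        img[, c0] <- stats::approx(rseq, img[, c0], xout = rseq - off[c0],
                                   yleft = 0, yright = 0)$y
      }
    }

    vr <- exp(-(seq_len(rows) - (rows + 1) / 2)^2 / (2 * (0.5 * rows)^2))
    vc <- exp(-(seq_len(cols) - (cols + 1) / 2)^2 / (2 * (0.5 * cols)^2))
    img <- img + spec$background_base + spec$vignette_amp * outer(vr, vc)

    if (spec$skew_deg != 0) {
      img <- .rotate_raster(img, spec$skew_deg, fill = spec$background_base)
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(rows * cols, sd = spec$noise_sd),
                          rows, cols)
    }
    for (sp in spec$specks) {
      rr <- pmax(1L, round(sp$row - 4 * sp$width)):
        pmin(rows, round(sp$row + 4 * sp$width))
      cc <- pmax(1L, round(sp$col - 4 * sp$width)):
        pmin(cols, round(sp$col + 4 * sp$width))
      img[rr, cc] <- img[rr, cc] + sp$amplitude *
        exp(-(outer((rr - sp$row)^2, (cc - sp$col)^2, "+")) /
              (2 * sp$width^2))
    }

    img <- pmin(pmax(img, 0), 1)
    raw <- 1 - img
    if (spec$quantize) raw <- round(raw * 65535) / 65535
    gel <- gel_image(raw, bit_depth = 16L, inverted = FALSE,
                     saturation_fraction = mean(raw >= 1),
                     source = "synthetic")

    a <- spec$migration[["a"]]; b <- spec$migration[["b"]]
    sizes <- spec$ladder$band_sizes
    centers <- c(spec$ladder_cols[1L], spec$sample_cols,
                 spec$ladder_cols[-1L])
    roles <- c("ladder", rep("sample", length(spec$sample_cols)),
               rep("ladder", length(spec$ladder_cols) - 1L))
    labels <- character(length(centers))
    labels[roles == "ladder"] <- sprintf("ladder%d", seq_len(sum(roles == "ladder")))
    labels[roles == "sample"] <- sprintf("sample%d", seq_len(sum(roles == "sample")))
    off_at <- function(c0) {
      if (spec$shear_px == 0) 0
      else spec$shear_px * ((c0 - 1) / (cols - 1) - 0.5)
    }
    band_rows <- matrix(NA_real_, length(sizes), length(centers),
                        dimnames = list(as.character(sizes), labels))
    for (k in seq_along(sizes)) {
      for (j in seq_along(centers)) {
        r0 <- a + b * log10(sizes[k]) + off_at(centers[j])
        band_rows[k, j] <- .rotate_point(r0, centers[j], rows, cols,
                                         spec$skew_deg)[1L]
      }
    }
    pct <- outer(seq_along(spec$sample_cols), sizes,
                 Vectorize(function(i, s) true_percent_above(spec, i, s)))
    dimnames(pct) <- list(labels[roles == "sample"], as.character(sizes))

    structure(list(
      gel = gel,
      truth = list(percent_above = pct, band_rows = band_rows,
                   lane_centers = centers, roles = roles, labels = labels)
    ), class = "synthetic_gel")
  })
}

#' Lane boxes matching a synthetic gel's layout
#'
#' @param spec A [synthetic_gel_spec()].
#' @param gel The rendered [gel_image()] (for bounds checking).
#' @return List of [define_lane()] boxes in left-to-right order, labelled
#'   as in the rendered ground truth.
#' @export
spec_lane_boxes <- function(spec, gel) {
  centers <- c(spec$ladder_cols[1L], spec$sample_cols, spec$ladder_cols[-1L])
  roles <- c("ladder", rep("sample", length(spec$sample_cols)),
             rep("ladder", length(spec$ladder_cols) - 1L))
  labels <- character(length(centers))
  labels[roles == "ladder"] <- sprintf("ladder%d", seq_len(sum(roles == "ladder")))
  labels[roles == "sample"] <- sprintf("sample%d", seq_len(sum(roles == "sample")))
  lapply(seq_along(centers), function(i) {
    define_lane(gel, centers[i], spec$lane_width, spec$row_top,
                spec$row_bottom, role = roles[i], label = labels[i])
  })
}

#' Time-degrade a synthetic gel specification
#'
#' Emulates postmortem DNA degradation: the intact mixture weight decays
#' exponentially with time and the degraded smear shifts to smaller
#' fragments. At `hours = 0` the specification is returned unchanged.
#'
#' @param spec A [synthetic_gel_spec()].
#' @param hours Non-negative time at room temperature.
#' @param k Decay rate of the intact fraction, per hour.
#' @param mu_shift Downward shift of the degraded component's meanlog, per
#'   hour.
#' @return The degraded [synthetic_gel_spec()].
#' @export
degrade <- function(spec, hours, k = 0.15, mu_shift = 0.03) {
  if (hours < 0) {
    .stop_gelquant("hours must be >= 0", "gelquant_parameter_error")
  }
  spec$w_intact <- spec$w_intact * exp(-k * hours)
  spec$deg_meanlog <- spec$deg_meanlog - mu_shift * hours
  spec
}

#' Draw a random synthetic gel specification
#'
#' Samples the per-lane degradation state (intact weight, smear location
#' and width) and mild geometric distortions from realistic ranges, at the
#' default noise level. Used for recovery and oracle-equivalence studies.
#'
#' @param seed Integer seed; also becomes the rendering seed.
#' @param n_samples Number of sample lanes (default 4; lane columns are
#'   spread evenly between the ladders).
#' @return A [synthetic_gel_spec()].
#' @export
random_gel_spec <- function(seed, n_samples = 4L) {
  .with_seed(seed, {
    sample_cols <- round(seq(132, 348, length.out = n_samples))
    synthetic_gel_spec(
      sample_cols = sample_cols,
      w_intact = stats::runif(n_samples),
      deg_meanlog = log(stats::runif(n_samples, 800, 8000)),
      deg_sdlog = stats::runif(n_samples, 0.5, 1.0),
      skew_deg = stats::runif(1, -1, 1),
      shear_px = stats::runif(1, -4, 4),
      seed = seed)
  })
}
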
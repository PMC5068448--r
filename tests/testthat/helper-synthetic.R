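# Shared fixtures: one default rendered gel reused across test files, plus
# small oracle helpers kept independent of the package's own integration
# and rendering paths.

default_spec <- synthetic_gel_spec()
default_sg <- render_gel(default_spec)
default_boxes <- spec_lane_boxes(default_spec, default_sg$gel)
default_score <- score_gel(default_sg$gel, default_boxes)

# Rectangular per-row pixel-sum oracle for region areas: Riemann sum of the
# lane-box column means, the threshold row's value shared between regions.
oracle_areas <- function(profile, threshold_row) {
  v <- profile$values
  r <- profile$rows
  t_idx <- which.min(abs(r - threshold_row))
  above <- sum(v[seq_len(t_idx - 1L)]) + v[t_idx] / 2
  below <- v[t_idx] / 2 + sum(v[seq.int(t_idx + 1L, length(v))])
  c(above = above, below = below)
}

# Analytic lane mass-per-row oracle: mixture CDF differences across row
# bins, tails absorbed at the clamp rows, then discrete Gaussian blur
# (written independently of the simulator's internals).
oracle_lane_profile <- function(spec, lane) {
  a <- spec$migration[["a"]]; b <- spec$migration[["b"]]
  edges <- 0:spec$rows
  s <- 10^((edges - a) / b)
  s[1] <- Inf; s[length(s)] <- 0
  w <- spec$w_intact[lane]
  FF <- function(x) w * plnorm(x, spec$intact_meanlog[lane],
                               spec$intact_sdlog[lane]) +
    (1 - w) * plnorm(x, spec$deg_meanlog[lane], spec$deg_sdlog[lane])
  mass <- FF(s[-length(s)]) - FF(s[-1])
  ct <- spec$clamp_top; cb <- spec$clamp_bottom
  mass[ct] <- mass[ct] + sum(mass[1:(ct - 1)]); mass[1:(ct - 1)] <- 0
  mass[cb] <- mass[cb] + sum(mass[(cb + 1):spec$rows])
  mass[(cb + 1):spec$rows] <- 0
  k_r <- ceiling(4 * spec$band_sigma)
  kern <- dnorm(-k_r:k_r, sd = spec$band_sigma)
  kern <- kern / sum(kern)
  n <- length(mass)
  padded <- c(numeric(k_r), mass, numeric(k_r))
  out <- vapply(seq_len(n), function(i) {
    sum(padded[i:(i + 2 * k_r)] * rev(kern))
  }, numeric(1))
  spec$lane_mass[lane] * out
}
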
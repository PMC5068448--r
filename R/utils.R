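# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.trapz <- function(v) {
  n <- length(v)
  if (n < 2L) return(0)
  sum((v[-1L] + v[-n]) / 2)
}

# Local maxima with topographic prominence. A point is a peak when strictly
# greater than its left neighbour and >= its right neighbour (so plateaus
# yield their leftmost point). Prominence: height minus the higher of the
# two key saddles, each saddle being the minimum between the peak and the
# nearest position (or edge) at least as high as the peak.
#' @noRd
.find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) {
    return(data.frame(index = integer(), height = numeric(),
                      prominence = numeric()))
  }
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(idx)) {
    return(data.frame(index = integer(), height = numeric(),
                      prominence = numeric()))
  }
  prom <- vapply(idx, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    higher <- which(left >= h)
    lmin <- if (length(higher)) min(left[(max(higher)):(i - 1L)]) else min(left)
    right <- x[(i + 1L):n]
    higher <- which(right >= h)
    rmin <- if (length(higher)) min(right[seq_len(min(higher))]) else min(right)
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(index = idx[keep], height = x[idx[keep]], prominence = prom[keep])
}

# Discrete Gaussian smoothing (zero-padded); kernel normalised so that total
# signal is conserved away from the vector ends.
#' @noRd
.gaussian_blur1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(numeric(r), x, numeric(r))
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

# Running mean with window half-width r (edges use the available window).
#' @noRd
.running_mean <- function(x, r) {
  if (r <= 0) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - r, 1L)
  hi <- pmin(seq_len(n) + r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' @noRd
.stop_gelquant <- function(msg, class) {
  stop(structure(class = c(class, "gelquant_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Evaluate an expression with a private RNG stream, restoring the caller's
# .Random.seed afterwards.
#' @noRd
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
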
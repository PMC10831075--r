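# Internal numerical helpers shared across modules.

# Robust noise estimate for an intensity trace: scaled median absolute
# deviation about a running median. The running median tracks baseline and
# broad structure; sparse narrow peaks barely move a MAD. Unlike a
# first-difference estimator this stays scale-correct when smoothing has
# correlated neighbouring samples.
noise_estimate <- function(intensity, k = 31L) {
  n <- length(intensity)
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  if (k < 3L) return(stats::mad(intensity, constant = 1.4826))
  resid <- intensity - stats::runmed(intensity, k)
  stats::mad(resid, center = 0, constant = 1.4826)
}

# Local background of a trace: a wide running median. Narrow peaks barely
# move it, so apex minus background is the peak's prominence above whatever
# pedestal (e.g. the noise floor left by a morphological opening) remains.
# The window spans `width_rel` of the mid-range m/z (default 1%), an order
# of magnitude wider than the 0.1% peak widths, whatever the grid spacing.
local_background <- function(intensity, mz = NULL, width_rel = 0.01) {
  n <- length(intensity)
  k <- if (is.null(mz)) 31L else {
    step <- median(diff(mz))
    as.integer(ceiling(width_rel * median(mz) / step))
  }
  k <- max(k, 3L)
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  if (k < 3L) return(rep(median(intensity), n))
  stats::runmed(intensity, k)
}

# Expected max - min of n i.i.d. standard normal draws (asymptotic).
# Used by the flatline rule so that "threshold x noise" is measured
# against what pure noise alone would produce on a trace of that length.
expected_noise_range <- function(n) 2 * sqrt(2 * log(max(n, 2L)))

# Apex refinement: fit a parabola through log intensity at the maximum and
# its two neighbours. For a Gaussian peak sampled on any grid this recovers
# the true apex height and position exactly (log of a Gaussian is quadratic).
# Falls back to the raw maximum when the three points do not bracket a peak
# or are not all positive.
refine_apex <- function(mz, intensity, i) {
  n <- length(intensity)
  if (i <= 1L || i >= n) {
    return(list(mz = mz[i], height = intensity[i]))
  }
  y <- intensity[(i - 1L):(i + 1L)]
  if (any(y <= 0) || y[2L] < y[1L] || y[2L] < y[3L]) {
    return(list(mz = mz[i], height = intensity[i]))
  }
  ly <- log(y)
  x <- mz[(i - 1L):(i + 1L)]
  # quadratic through three (possibly non-uniform) abscissae
  d1 <- (ly[2L] - ly[1L]) / (x[2L] - x[1L])
  d2 <- (ly[3L] - ly[2L]) / (x[3L] - x[2L])
  a <- (d2 - d1) / (x[3L] - x[1L])
  if (a >= 0) {
    return(list(mz = mz[i], height = intensity[i]))
  }
  b <- d1 - a * (x[1L] + x[2L])
  xv <- -b / (2 * a)
  if (xv < x[1L] || xv > x[3L]) {
    return(list(mz = mz[i], height = intensity[i]))
  }
  c0 <- ly[1L] - a * x[1L]^2 - b * x[1L]
  list(mz = xv, height = exp(a * xv^2 + b * xv + c0))
}

# Indices of strict-or-plateau local maxima of a trace.
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
}

# Validate a single spectrum tibble (columns mz, intensity).
check_spectrum <- function(s, arg = "spectrum") {
  if (!is.data.frame(s) || !all(c("mz", "intensity") %in% names(s))) {
    abort(sprintf("`%s` must be a data frame with columns `mz` and `intensity`.", arg))
  }
  if (nrow(s) < 2L) abort(sprintf("`%s` must contain at least 2 points.", arg))
  if (any(!is.finite(s$mz)) || any(s$mz <= 0)) {
    abort(sprintf("`%s` has non-finite or non-positive m/z values.", arg))
  }
  if (any(!is.finite(s$intensity))) {
    abort(sprintf("`%s` has non-finite intensities.", arg))
  }
  if (any(diff(s$mz) <= 0)) {
    abort(sprintf("`%s` must have a strictly increasing m/z axis.", arg))
  }
  invisible(s)
}

# Validate a batch of spectra: tibble with list-column `spectrum`.
check_batch <- function(batch, arg = "spectra") {
  if (!is.data.frame(batch) || !("spectrum" %in% names(batch))) {
    abort(sprintf("`%s` must be a spectra tibble with a `spectrum` list-column.", arg))
  }
  invisible(batch)
}

# Map over the spectrum list-column, replacing it.
map_spectra <- function(batch, f, ...) {
  batch$spectrum <- purrr::map(batch$spectrum, f, ...)
  batch
}

# Derive a bounded child seed from a base seed and a stream label, so one
# global seed can drive several independent stochastic stages.
child_seed <- function(seed, stream) {
  (as.integer(seed) %% 599999L) * 3001L + as.integer(stream) * 7L + 13L
}
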
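# Preprocessing chain: quality control, crop + resample, smoothing, top-hat
# baseline subtraction, TIC normalisation, ppm recalibration.

#' Flag flatline and outlier spectra
#'
#' A spectrum is a *flatline* when its intensity range does not exceed
#' `noise_threshold` times the range a pure-noise trace of the same length
#' would show (robust noise estimate times the expected extreme range), i.e.
#' nothing rises meaningfully above noise. It is an *outlier* when its maximum
#' exceeds `outlier_multiplier` times the trimmed (median) per-spectrum
#' maximum of the batch.
#'
#' @param batch Spectra tibble.
#' @param noise_threshold Multiplier on the noise-only range (default 2).
#' @param outlier_multiplier Multiplier on the batch trimmed maximum
#'   (default 10).
#' @return `batch` with a `qc` column: `"pass"`, `"flatline"` or `"outlier"`.
#' @export
assess_quality <- function(batch, noise_threshold = 2, outlier_multiplier = 10) {
  check_batch(batch)
  stats <- purrr::map(batch$spectrum, function(s) {
    rng <- max(s$intensity) - min(s$intensity)
    list(rng = rng,
         noise = noise_estimate(s$intensity),
         n = nrow(s),
         top = max(s$intensity))
  })
  tops <- purrr::map_dbl(stats, "top")
  trimmed_max <- median(tops)
  batch$qc <- purrr::map_chr(stats, function(st) {
    if (st$rng <= noise_threshold * st$noise * expected_noise_range(st$n)) {
      "flatline"
    } else if (st$top > outlier_multiplier * trimmed_max) {
      "outlier"
    } else {
      "pass"
    }
  })
  batch
}

#' Analysis grid for cropped spectra
#'
#' A geometric (constant relative step) m/z grid over `mass_window`, with
#' relative spacing `1 / (resolution * oversample)`. `resolution` is the
#' resolving power m/dm the grid must support; `oversample` is the number of
#' grid points per resolution element. On this grid a peak whose width is a
#' fixed fraction of its m/z covers the same number of points everywhere,
#' so smoothing and apex reading treat all peaks identically.
#'
#' @param mass_window `(low, high)` in Da.
#' @param resolution Resolving power (default 800).
#' @param oversample Points per resolution element (default 6).
#' @return Numeric vector of grid m/z values (endpoints included).
#' @export
resample_grid <- function(mass_window = c(2000, 15000), resolution = 800,
                          oversample = 6) {
  r <- 1 / (resolution * oversample)
  n <- ceiling(log(mass_window[2L] / mass_window[1L]) / log1p(r))
  g <- mass_window[1L] * (1 + r)^(0:n)
  g[length(g)] <- mass_window[2L]
  g
}

#' Crop spectra to the analysis window and resample onto a common grid
#'
#' Restricts each spectrum to `mass_window` and linearly interpolates it onto
#' the [resample_grid()]. Resampling is a projection: applying it twice gives
#' the same result, and affine intensity profiles are reproduced exactly.
#'
#' @inheritParams assess_quality
#' @inheritParams resample_grid
#' @return The batch on the common grid.
#' @export
crop_resample <- function(batch, mass_window = c(2000, 15000),
                          resolution = 800, oversample = 6) {
  check_batch(batch)
  grid <- resample_grid(mass_window, resolution, oversample)
  map_spectra(batch, function(s) {
    if (s$mz[1L] > mass_window[1L] || s$mz[nrow(s)] < mass_window[2L]) {
      abort("`mass_window` extends beyond the spectrum's m/z range.")
    }
    tibble(mz = grid,
           intensity = approx(s$mz, s$intensity, xout = grid)$y)
  })
}

#' Savitzky-Golay smoothing
#'
#' @inheritParams assess_quality
#' @param window Filter length in points (odd, default 9).
#' @param order Polynomial order (default 3).
#' @return The smoothed batch.
#' @export
smooth_spectra <- function(batch, window = 9, order = 3) {
  check_batch(batch)
  map_spectra(batch, function(s) {
    s$intensity <- signal::sgolayfilt(s$intensity, p = order, n = window)
    s
  })
}

#' Top-hat morphological baseline of a single spectrum
#'
#' The baseline is the morphological opening of the intensity trace: an
#' erosion (running minimum) followed by a dilation (running maximum) with a
#' flat structuring element of width `window` Da. The opening never exceeds
#' the input, so `corrected = intensity - baseline` is non-negative and
#' `corrected + baseline` reconstructs the input exactly. Features narrower
#' than the window (peaks) are removed from the baseline; slowly varying
#' background is retained in it.
#'
#' @param s Spectrum tibble `(mz, intensity)`.
#' @param window Structuring element width in Da (must span more than two
#'   grid steps).
#' @return A list with `corrected` and `baseline` spectrum tibbles.
#' @export
top_hat_baseline <- function(s, window = 150) {
  check_spectrum(s)
  if (window <= 0) abort("`window` must be positive.")
  if (window < 2 * min(diff(s$mz))) {
    abort("`window` must span at least two grid steps.")
  }
  half <- window / 2
  eroded <- .run_min(s$mz, s$intensity, half)
  opened <- .run_max(s$mz, eroded, half)
  list(
    corrected = tibble(mz = s$mz, intensity = s$intensity - opened),
    baseline = tibble(mz = s$mz, intensity = opened)
  )
}

#' Subtract the top-hat baseline from every spectrum in a batch
#'
#' @inheritParams assess_quality
#' @inheritParams top_hat_baseline
#' @return The baseline-corrected batch.
#' @export
subtract_baseline <- function(batch, window = 150) {
  check_batch(batch)
  map_spectra(batch, function(s) top_hat_baseline(s, window)$corrected)
}

#' Total-ion-count normalisation
#'
#' Divides intensities by their sum and multiplies by `scale`, so every
#' spectrum's total intensity equals `scale`. Invariant under prior
#' multiplication of the input by any positive constant.
#'
#' @param x A spectra batch or a single spectrum tibble.
#' @param scale Target total intensity (default 100).
#' @return Object of the same shape, normalised.
#' @export
normalize_tic <- function(x, scale = 100) {
  norm1 <- function(s) {
    tot <- sum(s$intensity)
    if (tot <= 0) abort("Cannot TIC-normalise a spectrum with non-positive total intensity.")
    s$intensity <- s$intensity * (scale / tot)
    s
  }
  if (is.data.frame(x) && "spectrum" %in% names(x)) {
    map_spectra(x, norm1)
  } else {
    norm1(check_spectrum(x))
  }
}

#' Recalibrate the mass axes of a batch against a reference peak list
#'
#' For each spectrum, local maxima with signal-to-noise at least `snr` are
#' matched to the reference peak centres within `max_shift_ppm`. Spectra whose
#' matched fraction of reference peaks falls below `min_match` are marked
#' `"excluded"`. For the rest, a single multiplicative mass-axis correction
#' (the median relative shift of the matched pairs) is applied and the
#' spectrum is re-interpolated onto its original grid, so all accepted
#' spectra stay on a common axis.
#'
#' @inheritParams assess_quality
#' @param reference A peak list tibble (see [pick_peaks()]) or numeric vector
#'   of reference masses.
#' @param max_shift_ppm Maximal tolerated peak shift in ppm (default 1000).
#' @param min_match Minimal matched fraction of reference peaks (default 0.30).
#' @param snr Signal-to-noise threshold for the matching maxima.
#' @return `batch` with columns `shift_ppm` (the applied correction) and
#'   `calibration` (`"accepted"` / `"excluded"`); accepted spectra corrected.
#' @export
recalibrate <- function(batch, reference, max_shift_ppm = 1000,
                        min_match = 0.30, snr = 5) {
  check_batch(batch)
  ref <- if (is.data.frame(reference)) reference$center else as.numeric(reference)
  if (!length(ref)) abort("`reference` peak list is empty.")
  out <- purrr::map(batch$spectrum, function(s) {
    noise <- noise_estimate(s$intensity)
    cand_idx <- local_maxima(s$intensity)
    cand_idx <- cand_idx[s$intensity[cand_idx] >= snr * noise]
    cand <- purrr::map_dbl(cand_idx, ~ refine_apex(s$mz, s$intensity, .x)$mz)
    shifts <- purrr::map_dbl(ref, function(m) {
      if (!length(cand)) return(NA_real_)
      d <- (cand - m) / m
      j <- which.min(abs(d))
      if (abs(d[j]) * 1e6 <= max_shift_ppm) d[j] else NA_real_
    })
    frac <- mean(!is.na(shifts))
    if (frac < min_match) {
      return(list(spectrum = s, shift_ppm = NA_real_, calibration = "excluded"))
    }
    delta <- median(shifts, na.rm = TRUE)
    corrected_axis <- s$mz / (1 + delta)
    s$intensity <- approx(corrected_axis, s$intensity, xout = s$mz, rule = 2)$y
    list(spectrum = s, shift_ppm = delta * 1e6, calibration = "accepted")
  })
  batch$spectrum <- purrr::map(out, "spectrum")
  batch$shift_ppm <- purrr::map_dbl(out, "shift_ppm")
  batch$calibration <- purrr::map_chr(out, "calibration")
  batch
}
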
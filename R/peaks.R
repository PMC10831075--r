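# Total average spectrum, peak picking at a signal-to-noise threshold, and
# extraction of the labelled spectra x peaks intensity matrix.

format_mass <- function(mass) sprintf("mz_%.2f", mass)

new_peak_matrix <- function(df, centres) {
  df <- as_tibble(df)
  attr(df, "peak_centers") <- as.numeric(centres)
  class(df) <- c("peak_matrix", setdiff(class(df), "peak_matrix"))
  df
}

#' Peak centres of a peak-intensity matrix
#' @param m A peak-matrix tibble.
#' @return Numeric vector of peak centre masses (Da), one per intensity column.
#' @export
peak_centers <- function(m) attr(m, "peak_centers")

#' Intensity block of a peak-intensity matrix
#' @param m A peak-matrix tibble.
#' @return Numeric matrix (spectra x peaks), columns named by mass.
#' @export
intensity_values <- function(m) {
  cols <- setdiff(names(m), c("strain", "replicate"))
  as.matrix(m[cols])
}

#' Total average spectrum of a batch
#'
#' Pointwise arithmetic mean over spectra sharing one grid. With
#' `class_average = TRUE` the classes are averaged first and then averaged
#' together, weighting every class equally regardless of replicate counts.
#'
#' @inheritParams assess_quality
#' @param class_average Average within strain first? Default `FALSE` (every
#'   spectrum weighted equally).
#' @return A spectrum tibble `(mz, intensity)`.
#' @export
average_spectrum <- function(batch, class_average = FALSE) {
  check_batch(batch)
  if (!nrow(batch)) abort("Empty batch.")
  grids <- purrr::map(batch$spectrum, "mz")
  if (!all(purrr::map_lgl(grids, ~ isTRUE(all.equal(.x, grids[[1L]]))))) {
    abort("Spectra are not on a common grid; run crop_resample() first.")
  }
  mean_of <- function(specs) {
    rowMeans(do.call(cbind, purrr::map(specs, "intensity")))
  }
  if (class_average && "strain" %in% names(batch)) {
    per_class <- batch |>
      group_by(.data$strain) |>
      dplyr::group_map(~ mean_of(.x$spectrum))
    y <- rowMeans(do.call(cbind, per_class))
  } else {
    y <- mean_of(batch$spectrum)
  }
  tibble(mz = grids[[1L]], intensity = y)
}

#' Pick peaks on a baseline-corrected spectrum
#'
#' Local maxima whose apex is at least `snr_threshold` times the robust noise
#' estimate become peaks. Each peak's integration window runs to the flanking
#' local minima, capped at half the distance to the neighbouring peak and at
#' `max_halfwidth_rel` times the centre mass, so windows never overlap.
#' Apex positions are refined by a log-quadratic fit through the three points
#' around the maximum (exact for Gaussian peaks).
#'
#' @param avg Spectrum tibble (typically the total average spectrum).
#' @param snr_threshold Signal-to-noise threshold (default 5).
#' @param max_halfwidth_rel Cap on the window half width as a fraction of the
#'   peak mass (default 0.003).
#' @return A peak-list tibble with columns `center`, `left`, `right`, `snr`
#'   (empty when nothing exceeds the threshold).
#' @export
pick_peaks <- function(avg, snr_threshold = 5, max_halfwidth_rel = 0.003) {
  check_spectrum(avg)
  y <- avg$intensity
  mz <- avg$mz
  noise <- noise_estimate(y)
  bg <- local_background(y, mz)
  idx <- local_maxima(y)
  # signal-to-noise of the apex prominence above the local background
  if (noise > 0) idx <- idx[(y[idx] - bg[idx]) >= snr_threshold * noise]
  idx <- idx[y[idx] > 0]
  if (!length(idx)) {
    return(tibble(center = double(), left = double(),
                  right = double(), snr = double()))
  }
  n <- length(y)
  refined <- purrr::map(idx, ~ refine_apex(mz, y, .x))
  centres <- purrr::map_dbl(refined, "mz")
  # windows: walk to flanking minima
  lefts <- rights <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    l <- i
    while (l > 1L && y[l - 1L] < y[l]) l <- l - 1L
    r <- i
    while (r < n && y[r + 1L] < y[r]) r <- r + 1L
    lefts[k] <- mz[l]
    rights[k] <- mz[r]
  }
  # cap at half-distance to neighbouring peak and at the relative half width
  for (k in seq_along(idx)) {
    cap <- max_halfwidth_rel * centres[k]
    lefts[k] <- max(lefts[k], centres[k] - cap,
                    if (k > 1L) (centres[k] + centres[k - 1L]) / 2 else -Inf)
    rights[k] <- min(rights[k], centres[k] + cap,
                     if (k < length(idx)) (centres[k] + centres[k + 1L]) / 2 else Inf)
  }
  tibble(center = centres, left = lefts, right = rights,
         snr = if (noise > 0) (y[idx] - bg[idx]) / noise else Inf)
}

#' Extract the labelled spectra x peaks intensity matrix
#'
#' Entry (i, j) is the apex intensity of spectrum i inside peak j's window:
#' the maximum over the window, refined by the log-quadratic apex fit, as a
#' prominence above the spectrum's local (running-median) background so the
#' residual noise pedestal after baseline subtraction does not bias reads.
#'
#' @inheritParams assess_quality
#' @param peaks A peak-list tibble from [pick_peaks()].
#' @return A peak-matrix tibble: `strain`, `replicate`, one column per peak
#'   (named by centre mass), with the centres in `peak_centers()`.
#' @export
peak_matrix <- function(batch, peaks) {
  check_batch(batch)
  if (!nrow(peaks)) abort("Empty peak list.")
  vals <- purrr::map(batch$spectrum, function(s) {
    bg <- local_background(s$intensity, s$mz)
    purrr::map_dbl(seq_len(nrow(peaks)), function(j) {
      win <- which(s$mz >= peaks$left[j] & s$mz <= peaks$right[j])
      if (!length(win)) return(0)
      i <- win[which.max(s$intensity[win])]
      max(refine_apex(s$mz, s$intensity, i)$height - bg[i], 0)
    })
  })
  m <- do.call(rbind, vals)
  colnames(m) <- format_mass(peaks$center)
  meta <- batch[intersect(c("strain", "replicate"), names(batch))]
  new_peak_matrix(bind_cols(as_tibble(meta), as_tibble(m)), peaks$center)
}

#' Read apex intensities at known peak positions
#'
#' Convenience extraction for generator checks: for each nominal mass, the
#' apex (maximum plus log-quadratic refinement) within `halfwidth_rel` times
#' the mass around it.
#'
#' @inheritParams assess_quality
#' @param masses Nominal peak masses (Da).
#' @param halfwidth_rel Search half width relative to the mass.
#' @return A peak-matrix tibble as from [peak_matrix()].
#' @export
apex_intensities <- function(batch, masses, halfwidth_rel = 0.003) {
  peaks <- tibble(center = sort(as.numeric(masses))) |>
    mutate(left = .data$center * (1 - halfwidth_rel),
           right = .data$center * (1 + halfwidth_rel))
  peak_matrix(batch, peaks)
}
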
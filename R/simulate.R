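# Synthetic replicate spectra with the statistical structure the analysis
# assumes: Gaussian peaks whose apex heights are truncated-Normal draws per
# strain, a smooth positive baseline, white noise, and a per-replicate global
# ppm mass shift (what recalibration later corrects).

# Truncated Normal(mean, sd) on [0, Inf) by inverse-CDF sampling; a fixed
# number of uniforms per call keeps the RNG stream aligned across cells.
# Vectorised over mean and sd; sd = 0 cells return their mean.
rtnorm0 <- function(n, mean, sd) {
  u <- runif(n)
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    lo <- pnorm(0, mean[pos], sd[pos])
    out[pos] <- qnorm(lo + u[pos] * (1 - lo), mean[pos], sd[pos])
  }
  out
}

render_trace <- function(mz, profile, heights, delta) {
  y <- numeric(length(mz))
  for (j in seq_len(nrow(profile))) {
    h <- heights[j]
    if (h <= 0) next
    centre <- profile$mass[j] * (1 + delta)
    sigma <- profile$fwhm[j] / (2 * sqrt(2 * log(2)))
    win <- which(mz >= centre - 6 * sigma & mz <= centre + 6 * sigma)
    if (length(win)) {
      y[win] <- y[win] + h * exp(-(mz[win] - centre)^2 / (2 * sigma^2))
    }
  }
  y
}

baseline_drift <- function(mz, amplitude) {
  u <- (mz - mz[1L]) / (mz[length(mz)] - mz[1L])
  c1 <- runif(1, 0.5, 1)
  c2 <- runif(1, 0.5, 1)
  amplitude * (c1 * exp(-2 * u) + c2 * (1 - u))
}

#' Simulate replicate MALDI-TOF spectra for a set of strain profiles
#'
#' Renders `n_replicates` linear-mode spectra per strain on a uniform m/z
#' grid. Each profile peak becomes a Gaussian whose apex height is drawn from
#' Normal(mean, sd) truncated at zero; a per-replicate global mass shift drawn
#' uniformly within `ppm_jitter_max` ppm displaces all peak centres (the
#' acquisition drift that recalibration corrects); a smooth positive baseline
#' and i.i.d. Normal(0, `noise_sd`) noise are added. Identical arguments give
#' bit-identical output.
#'
#' @param profiles A [strain_profiles()] tibble.
#' @param n_replicates Spectra per strain (default 15, three biological times
#'   five technical spots).
#' @param mass_range Acquisition window in Da.
#' @param grid_step Uniform grid spacing in Da. 0.25 Da keeps even the
#'   narrowest default peaks (FWHM 0.1% of m/z) sampled finely enough that
#'   downstream resampling reads their apexes to well under 1%.
#' @param noise_sd Standard deviation of the additive white noise (a.u.).
#' @param baseline_amplitude Scale of the smooth baseline drift (a.u.); small
#'   relative to discriminant peak heights so top-hat removal is exercised but
#'   never dominates.
#' @param ppm_jitter_max Half-range of the per-replicate uniform mass shift in
#'   ppm; must stay below the 1000 ppm recalibration cap.
#' @param seed Integer seed governing all randomness in this call.
#' @return A tibble with columns `strain`, `replicate` and a `spectrum`
#'   list-column of `(mz, intensity)` tibbles.
#' @export
#' @examples
#' batch <- simulate_replicates(reference_profiles("discriminant"),
#'                              n_replicates = 2, seed = 1)
simulate_replicates <- function(profiles,
                                n_replicates = 15,
                                mass_range = c(1960, 22000),
                                grid_step = 0.25,
                                noise_sd = 0.08,
                                baseline_amplitude = 0.3,
                                ppm_jitter_max = 300,
                                seed = 1) {
  if (!inherits(profiles, "strain_profiles")) profiles <- strain_profiles(profiles)
  if (grid_step <= 0) abort("`grid_step` must be positive.")
  if (mass_range[2L] <= mass_range[1L]) abort("`mass_range` is inverted.")
  if (ppm_jitter_max < 0 || ppm_jitter_max >= 1000) {
    abort("`ppm_jitter_max` must be in [0, 1000) ppm.")
  }
  if (noise_sd < 0 || baseline_amplitude < 0) {
    abort("`noise_sd` and `baseline_amplitude` must be non-negative.")
  }
  strains <- unique(profiles$strain)
  mz <- seq(mass_range[1L], mass_range[2L], by = grid_step)
  withr::with_seed(as.integer(seed), {
    rows <- purrr::map(strains, function(st) {
      prof <- profiles[profiles$strain == st, ]
      purrr::map(seq_len(n_replicates), function(r) {
        delta <- runif(1, -ppm_jitter_max, ppm_jitter_max) * 1e-6
        heights <- rtnorm0(nrow(prof), prof$mean, prof$sd)
        y <- render_trace(mz, prof, heights, delta)
        if (baseline_amplitude > 0) y <- y + baseline_drift(mz, baseline_amplitude)
        if (noise_sd > 0) y <- y + rnorm(length(mz), 0, noise_sd)
        tibble(strain = st, replicate = r,
               spectrum = list(tibble(mz = mz, intensity = y)))
      }) |> bind_rows()
    }) |> bind_rows()
    rows
  })
}

#' Simulate degenerate spectra for quality-control testing
#'
#' `"flatline"` spectra carry only baseline and noise (no peaks);
#' `"outlier_peaks"` spectra are ordinary replicates of the first profiled
#' strain with one injected spike whose apex is `spike_factor` times the
#' largest intensity the clean batch contains.
#'
#' @param kind `"flatline"` or `"outlier_peaks"`.
#' @param n Number of spectra.
#' @param profiles Profiles used for the `"outlier_peaks"` kind.
#' @param spike_mass m/z position of the injected spike.
#' @param spike_factor Spike apex relative to the clean batch maximum.
#' @inheritParams simulate_replicates
#' @return A spectra tibble as from [simulate_replicates()].
#' @export
simulate_degenerate <- function(kind = c("flatline", "outlier_peaks"),
                                n = 5,
                                profiles = reference_profiles("discriminant"),
                                mass_range = c(1960, 22000),
                                grid_step = 0.25,
                                noise_sd = 0.08,
                                baseline_amplitude = 0.3,
                                spike_mass = 8000,
                                spike_factor = 20,
                                seed = 1) {
  kind <- match.arg(kind)
  if (kind == "flatline") {
    mz <- seq(mass_range[1L], mass_range[2L], by = grid_step)
    return(withr::with_seed(as.integer(seed), {
      purrr::map(seq_len(n), function(r) {
        y <- numeric(length(mz))
        if (baseline_amplitude > 0) y <- y + baseline_drift(mz, baseline_amplitude)
        if (noise_sd > 0) y <- y + rnorm(length(mz), 0, noise_sd)
        tibble(strain = "flatline", replicate = r,
               spectrum = list(tibble(mz = mz, intensity = y)))
      }) |> bind_rows()
    }))
  }
  first_strain <- unique(profiles$strain)[1L]
  batch <- simulate_replicates(profiles[profiles$strain == first_strain, ],
                               n_replicates = n, mass_range = mass_range,
                               grid_step = grid_step, noise_sd = noise_sd,
                               baseline_amplitude = baseline_amplitude,
                               ppm_jitter_max = 0, seed = seed)
  top <- max(purrr::map_dbl(batch$spectrum, ~ max(.x$intensity)))
  sigma <- 0.001 * spike_mass / (2 * sqrt(2 * log(2)))
  batch$strain <- "outlier_peaks"
  map_spectra(batch, function(s) {
    win <- which(s$mz >= spike_mass - 6 * sigma & s$mz <= spike_mass + 6 * sigma)
    s$intensity[win] <- s$intensity[win] +
      spike_factor * top * exp(-(s$mz[win] - spike_mass)^2 / (2 * sigma^2))
    s
  })
}

#' Simulate a labelled peak-intensity matrix directly
#'
#' Bypasses the spectral stage and draws the apex-intensity matrix itself:
#' every strain/peak cell is a truncated Normal(mean, sd) draw. This is the
#' exact statistical model the full spectral pipeline recovers, at a fraction
#' of the cost, and is the input scale on which the classifier and
#' discriminant-statistics study conditions are defined.
#'
#' @inheritParams simulate_replicates
#' @param n_replicates Either a single count or a vector with one count per
#'   strain (in `unique(profiles$strain)` order), e.g. `c(21, 20, 20)`.
#' @return A peak-matrix tibble: columns `strain`, `replicate`, then one
#'   intensity column per profile mass (see [peak_matrix()]).
#' @export
#' @examples
#' m <- simulate_peak_matrix(reference_profiles("discriminant"), 15, seed = 1)
simulate_peak_matrix <- function(profiles, n_replicates = 15, seed = 1) {
  if (!inherits(profiles, "strain_profiles")) profiles <- strain_profiles(profiles)
  strains <- unique(profiles$strain)
  if (length(n_replicates) == 1L) {
    n_replicates <- rep(n_replicates, length(strains))
  }
  if (length(n_replicates) != length(strains)) {
    abort("`n_replicates` must be scalar or one count per strain.")
  }
  masses <- sort(unique(profiles$mass))
  withr::with_seed(as.integer(seed), {
    rows <- purrr::map2(strains, n_replicates, function(st, nr) {
      prof <- profiles[profiles$strain == st, ]
      prof <- prof[order(prof$mass), ]
      vals <- purrr::map(seq_len(nrow(prof)), function(j) {
        rtnorm0(nr, prof$mean[j], prof$sd[j])
      })
      m <- do.call(cbind, vals)
      colnames(m) <- format_mass(masses)
      bind_cols(tibble(strain = st, replicate = seq_len(nr)), as_tibble(m))
    }) |> bind_rows()
    new_peak_matrix(rows, masses)
  })
}
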
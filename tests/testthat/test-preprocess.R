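test_that("quality control flags flatlines and outliers but passes real spectra", {
  clean <- simulate_replicates(quant_profiles(), n_replicates = 3, seed = 6)
  flat <- simulate_degenerate("flatline", n = 5, seed = 6)
  spikes <- simulate_degenerate("outlier_peaks", n = 1, seed = 6)
  qc <- assess_quality(dplyr::bind_rows(clean, flat, spikes))
  expect_equal(qc$qc[qc$strain == "flatline"], rep("flatline", 5))
  expect_equal(qc$qc[qc$strain == "outlier_peaks"], "outlier")
  expect_true(all(qc$qc[!(qc$strain %in% c("flatline", "outlier_peaks"))] == "pass"))
  # an exactly constant spectrum is a flatline
  const <- tibble::tibble(strain = "x", replicate = 1L,
                          spectrum = list(tibble::tibble(mz = 1:100 + 2000,
                                                         intensity = rep(3, 100))))
  expect_equal(assess_quality(const)$qc, "flatline")
})

test_that("crop/resample is a projection and preserves affine intensities", {
  grid <- resample_grid(c(2000, 15000), 800, 4)
  rel <- diff(grid) / head(grid, -1)
  # constant relative spacing except the final clamped point
  expect_lt(max(abs(head(rel, -1) - 1 / 3200)), 1e-9)
  # affine ramp reproduced exactly
  ramp <- tibble::tibble(strain = "x", replicate = 1L,
                         spectrum = list(tibble::tibble(
                           mz = seq(1900, 15100, by = 0.5),
                           intensity = 2 + 0.001 * seq(1900, 15100, by = 0.5))))
  once <- crop_resample(ramp)
  s1 <- once$spectrum[[1]]
  expect_equal(s1$intensity, 2 + 0.001 * s1$mz, tolerance = 1e-10)
  # idempotence: resampling the resampled spectrum changes nothing
  twice <- crop_resample(once)
  expect_equal(twice$spectrum[[1]]$intensity, s1$intensity, tolerance = 1e-12)
  # window beyond the data errors
  expect_error(crop_resample(ramp, mass_window = c(1000, 15000)), "window")
})

test_that("top-hat baseline reconstructs exactly and matches the brute-force oracle", {
  zero <- tibble::tibble(mz = seq(2000, 2199), intensity = rep(0, 200))
  th <- top_hat_baseline(zero, window = 20)
  expect_equal(th$baseline$intensity, rep(0, 200))
  expect_equal(th$corrected$intensity, rep(0, 200))
  const <- tibble::tibble(mz = seq(2000, 2199), intensity = rep(4.2, 200))
  th <- top_hat_baseline(const, window = 20)
  expect_equal(th$baseline$intensity, rep(4.2, 200))
  expect_equal(th$corrected$intensity, rep(0, 200))

  # narrow Gaussian on a linear ramp: corrected recovers the peak within 1%
  mz <- seq(4000, 6000, by = 1)
  peak <- 10 * exp(-(mz - 5000)^2 / (2 * 4^2))
  ramp <- 1 + 0.002 * (mz - 4000)
  th <- top_hat_baseline(tibble::tibble(mz = mz, intensity = peak + ramp), 200)
  expect_lt(abs(max(th$corrected$intensity) - 10) / 10, 0.01)

  # oracle equivalence + exact reconstruction on random instances
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    x <- sort(runif(n, 0, 100))
    y <- rnorm(n) + 5 * sin(x / 7)
    w <- runif(1, 5, 30)
    s <- tibble::tibble(mz = x + 1000, intensity = y)
    th <- top_hat_baseline(s, w)
    expect_equal(th$baseline$intensity, brute_top_hat(x + 1000, y, w),
                 tolerance = 1e-12)
    expect_equal(th$corrected$intensity + th$baseline$intensity, y,
                 tolerance = 1e-12)
    expect_true(all(th$corrected$intensity >= -1e-12))
  }
  expect_error(top_hat_baseline(zero, window = 0.5), "grid steps")
})

test_that("TIC normalisation is idempotent, scale-invariant and exact", {
  set.seed(3)
  s <- tibble::tibble(mz = seq(2000, 2999), intensity = runif(1000, 0.1, 5))
  n1 <- normalize_tic(s)
  expect_equal(sum(n1$intensity), 100, tolerance = 1e-9)
  expect_equal(normalize_tic(n1)$intensity, n1$intensity, tolerance = 1e-12)
  s7 <- s
  s7$intensity <- s7$intensity * 7
  expect_equal(normalize_tic(s7)$intensity, n1$intensity, tolerance = 1e-12)
  zero <- tibble::tibble(mz = c(2000, 2001), intensity = c(0, 0))
  expect_error(normalize_tic(zero), "normalise")
})

test_that("recalibration recovers injected shifts and excludes gross ones", {
  b <- simulate_replicates(quant_profiles(), n_replicates = 3,
                           ppm_jitter_max = 0, seed = 13)
  pp <- preprocess_spectra(b, tic_scale = NULL)
  ref <- pick_peaks(average_spectrum(pp))
  # unshifted spectra: all accepted, correction essentially zero
  rc <- recalibrate(pp, ref)
  expect_true(all(rc$calibration == "accepted"))
  expect_lt(max(abs(rc$shift_ppm)), 20)

  shift_by <- function(s, ppm) {
    tibble::tibble(mz = s$mz,
                   intensity = approx(s$mz * (1 + ppm * 1e-6), s$intensity,
                                      xout = s$mz, rule = 2)$y)
  }
  shifted <- pp[1, ]
  shifted$spectrum[[1]] <- shift_by(pp$spectrum[[1]], 600)
  rc <- recalibrate(shifted, ref)
  expect_equal(rc$calibration, "accepted")
  expect_equal(rc$shift_ppm, 600, tolerance = 0.15)
  # residual shift of the corrected peaks below 50 ppm
  resid <- pick_peaks(rc$spectrum[[1]])
  near <- purrr::map_dbl(ref$center, function(m) {
    min(abs(resid$center - m) / m * 1e6)
  })
  expect_lt(median(near), 50)

  gross <- pp[1, ]
  gross$spectrum[[1]] <- shift_by(pp$spectrum[[1]], 2000)
  rc <- recalibrate(gross, ref)
  expect_equal(rc$calibration, "excluded")
  expect_error(recalibrate(pp, numeric(0)), "empty")
})

test_that("the pipeline preserves apex intensity ratios for noise-free input", {
  prof <- strain_profiles(data.frame(
    strain = "A", mass = c(2944, 2959, 5505, 9492),
    mean = c(20, 8, 5, 1), sd = 0
  ))
  b <- simulate_replicates(prof, n_replicates = 1, grid_step = 0.125,
                           noise_sd = 0, baseline_amplitude = 0,
                           ppm_jitter_max = 0, seed = 1)
  pp <- preprocess_spectra(b, tic_scale = 100)
  m <- apex_intensities(pp, prof$mass)
  v <- as.numeric(intensity_values(m))
  ratios <- v / v[1]
  expect_equal(ratios, c(20, 8, 5, 1) / 20, tolerance = 0.01)
})
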
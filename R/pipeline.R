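# End-to-end orchestration: simulate -> preprocess -> peaks -> statistics ->
# classifiers -> MSPs -> identification.

#' Preprocess a batch of raw spectra
#'
#' Applies the standard preparation chain: quality control (flatline/outlier
#' removal), cropping and resampling onto the common analysis grid,
#' Savitzky-Golay smoothing, top-hat baseline subtraction and total-ion-count
#' normalisation. Recalibration is a separate step ([recalibrate()]) because
#' it needs a reference peak list.
#'
#' @inheritParams assess_quality
#' @inheritParams crop_resample
#' @param smooth_window,smooth_order Savitzky-Golay parameters.
#' @param baseline_window Top-hat structuring element width (Da).
#' @param tic_scale Target total intensity; `NULL` skips normalisation.
#' @param drop_failed Drop spectra that fail quality control? Default `TRUE`.
#' @return The processed batch (with the `qc` column retained).
#' @export
preprocess_spectra <- function(batch,
                               mass_window = c(2000, 15000),
                               resolution = 800,
                               oversample = 6,
                               noise_threshold = 2,
                               outlier_multiplier = 10,
                               smooth_window = 9,
                               smooth_order = 3,
                               baseline_window = 150,
                               tic_scale = 100,
                               drop_failed = TRUE) {
  out <- assess_quality(batch, noise_threshold, outlier_multiplier)
  if (drop_failed) out <- filter(out, .data$qc == "pass")
  if (!nrow(out)) abort("No spectra passed quality control.")
  out <- crop_resample(out, mass_window, resolution, oversample)
  if (smooth_window > 1) out <- smooth_spectra(out, smooth_window, smooth_order)
  out <- subtract_baseline(out, baseline_window)
  if (!is.null(tic_scale)) out <- normalize_tic(out, tic_scale)
  out
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full strain-typing study replica
#'
#' Simulates replicate spectra for the profiled strains (a training set and
#' an independent external test set), preprocesses and recalibrates them,
#' builds the average peak list and intensity matrices, selects discriminant
#' peaks, fits the QC, SNN and GA_KNN classifier families, validates them on
#' the external set, builds an MSP library from the external replicates and
#' re-identifies the training replicates against it. One seed governs every
#' stochastic stage; a fixed seed reproduces the bundle exactly.
#'
#' @param profiles Strain profiles (default [reference_profiles()]).
#' @param n_train Training replicates per strain (default 15).
#' @param n_test External test replicates per strain, scalar or one count per
#'   strain (default `c(21, 20, 20)`).
#' @param seed Global seed.
#' @inheritParams preprocess_spectra
#' @param generator Named list of overrides passed to
#'   [simulate_replicates()] (e.g. `noise_sd`).
#' @param recal_max_shift_ppm,recal_min_match Recalibration settings.
#' @param snr Peak-picking signal-to-noise threshold (default 5).
#' @param alpha Discriminant-selection p-value cut-off (default 0.05).
#' @param qc_peaks,snn_peaks Peaks retained by the QC and SNN models.
#' @param ga_k GA_KNN neighbour settings to fit (default `c(1, 3, 5, 7)`).
#' @param ga_generations,ga_max_peaks GA settings (defaults 50 and 30).
#' @param msp_min_frequency Minimal MSP peak frequency.
#' @param tol_ppm Peak match/alignment tolerance.
#' @param out_dir If non-`NULL`, CSV/JSON outputs and a run manifest are
#'   written there.
#' @return A list with `peak_table` (discriminant peaks), `performance`
#'   (Table-2-style metrics per model and class), `pca`, `msp_library`,
#'   `identification` (per training replicate), `train_matrix`,
#'   `test_matrix`, `models` and `manifest`.
#' @export
run_study_replica <- function(profiles = reference_profiles(),
                              n_train = 15,
                              n_test = c(21, 20, 20),
                              seed = 1,
                              mass_window = c(2000, 15000),
                              resolution = 800,
                              oversample = 6,
                              smooth_window = 9,
                              baseline_window = 150,
                              tic_scale = 100,
                              generator = list(),
                              recal_max_shift_ppm = 1000,
                              recal_min_match = 0.30,
                              snr = 5,
                              alpha = 0.05,
                              qc_peaks = 4,
                              snn_peaks = 3,
                              ga_k = c(1, 3, 5, 7),
                              ga_generations = 50,
                              ga_max_peaks = 30,
                              msp_min_frequency = 0.25,
                              tol_ppm = 600,
                              out_dir = NULL) {
  if (!inherits(profiles, "strain_profiles")) profiles <- strain_profiles(profiles)
  strains <- unique(profiles$strain)
  if (length(n_test) == 1L) n_test <- rep(n_test, length(strains))

  sim <- function(n_by_strain, stream) {
    purrr::imap(setNames(n_by_strain, strains), function(nr, st) {
      args <- c(list(profiles = profiles[profiles$strain == st, ],
                     n_replicates = nr,
                     seed = child_seed(seed, stream + match(st, strains))),
                generator)
      do.call(simulate_replicates, args)
    }) |> bind_rows()
  }

  train_raw <- stage("simulate_train", sim(rep(n_train, length(strains)), 0L))
  test_raw <- stage("simulate_test", sim(n_test, 100L))

  prep <- function(b) {
    preprocess_spectra(b, mass_window = mass_window, resolution = resolution,
                       oversample = oversample, smooth_window = smooth_window,
                       baseline_window = baseline_window, tic_scale = tic_scale)
  }
  train <- stage("preprocess_train", prep(train_raw))
  test <- stage("preprocess_test", prep(test_raw))

  # provisional peak list for recalibration, then final list on the
  # recalibrated total average spectrum
  recal <- function(b, ref) {
    out <- recalibrate(b, ref, max_shift_ppm = recal_max_shift_ppm,
                       min_match = recal_min_match, snr = snr)
    filter(out, .data$calibration == "accepted")
  }
  prov_peaks <- stage("provisional_peaks",
                      pick_peaks(average_spectrum(train), snr_threshold = snr))
  train <- stage("recalibrate_train", recal(train, prov_peaks))
  test <- stage("recalibrate_test", recal(test, prov_peaks))

  avg <- stage("average_spectrum", average_spectrum(train))
  peaks <- stage("pick_peaks", pick_peaks(avg, snr_threshold = snr))
  train_m <- stage("train_matrix", peak_matrix(train, peaks))
  test_m <- stage("test_matrix", peak_matrix(test, peaks))

  peak_table <- stage("discriminant_stats",
                      select_characteristic_peaks(train_m, alpha = alpha))
  pca <- stage("pca", run_pca(train_m, n_components = 2))

  models <- stage("train_models", {
    ms <- list(QC = train_qc(train_m, max_peaks = qc_peaks),
               SNN = train_snn(train_m, max_peaks = snn_peaks,
                               seed = child_seed(seed, 200L)))
    for (k in ga_k) {
      ms[[sprintf("GA_KNN%d", k)]] <-
        train_ga_knn(train_m, k = k, max_peaks = ga_max_peaks,
                     n_generations = ga_generations,
                     seed = child_seed(seed, 300L + k))
    }
    ms
  })

  performance <- stage("external_validation", {
    purrr::imap(models, function(mod, nm) {
      external_validate(mod, test_m, tol_ppm = tol_ppm) |>
        mutate(model = nm,
               n_model_peaks = length(mod$peak_masses), .before = 1L)
    }) |> bind_rows()
  })

  lib <- stage("build_msps", {
    recs <- purrr::map(strains, function(st) {
      build_msp(filter(test, .data$strain == st), name = st,
                min_frequency = msp_min_frequency, tol_ppm = tol_ppm,
                snr = snr, seed = as.integer(seed))
    })
    msp_library(recs)
  })

  identification <- stage("identification", {
    purrr::map(seq_len(nrow(train)), function(i) {
      res <- identify_spectrum(train$spectrum[[i]], lib, tol_ppm = tol_ppm)
      tibble(strain = train$strain[i], replicate = train$replicate[i],
             top_match = res$record[1L], log_score = res$log_score[1L],
             category = res$category[1L])
    }) |> bind_rows()
  })

  manifest <- tibble(
    parameter = c("seed", "n_train", "n_test", "strains", "mass_window",
                  "resolution", "oversample", "smooth_window",
                  "baseline_window", "tic_scale", "snr", "alpha", "qc_peaks",
                  "snn_peaks", "ga_k", "ga_generations", "ga_max_peaks",
                  "msp_min_frequency", "tol_ppm",
                  names(generator)),
    value = c(seed, n_train, paste(n_test, collapse = "/"),
              paste(strains, collapse = "/"),
              paste(mass_window, collapse = "-"), resolution, oversample,
              smooth_window, baseline_window, tic_scale %||% "none", snr,
              alpha, qc_peaks, snn_peaks, paste(ga_k, collapse = "/"),
              ga_generations, ga_max_peaks, msp_min_frequency, tol_ppm,
              purrr::map_chr(generator, ~ paste(.x, collapse = "/"))) |>
      as.character()
  )

  bundle <- list(peak_table = peak_table, performance = performance,
                 pca = pca, msp_library = lib,
                 identification = identification,
                 train_matrix = train_m, test_matrix = test_m,
                 models = models, manifest = manifest)

  if (!is.null(out_dir)) {
    stage("write_outputs", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      readr::write_csv(peak_table, file.path(out_dir, "discriminant_peaks.csv"))
      readr::write_csv(performance, file.path(out_dir, "model_performance.csv"))
      readr::write_csv(identification, file.path(out_dir, "identification.csv"))
      write_peak_matrix(train_m, file.path(out_dir, "train_matrix.csv"))
      write_peak_matrix(test_m, file.path(out_dir, "test_matrix.csv"))
      write_msp_library(lib, file.path(out_dir, "msp_library.json"))
      readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
    })
  }
  bundle
}
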
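make_record <- function(name, mz, intensity, frequency = 1) {
  maldistrain:::new_msp_record(
    name = name,
    peaks = tibble::tibble(mz = mz, mean_intensity = intensity,
                           frequency = rep_len(frequency, length(mz))),
    n_source_spectra = 10L
  )
}

test_that("MSPs built from identical replicates carry every peak at frequency 1", {
  prof <- strain_profiles(data.frame(
    strain = "A", mass = c(3000, 5000, 8000), mean = c(10, 5, 2), sd = 0
  ))
  b <- simulate_replicates(prof, n_replicates = 4, noise_sd = 0,
                           baseline_amplitude = 0, ppm_jitter_max = 0, seed = 3) |>
    crop_resample()
  rec <- build_msp(b, name = "A")
  expect_equal(nrow(rec$peaks), 3L)
  expect_equal(rec$peaks$frequency, rep(1, 3))
  expect_equal(rec$peaks$mz, c(3000, 5000, 8000), tolerance = 1e-3)
  # relative intensities preserved (normalised to sum 100)
  expect_equal(rec$peaks$mean_intensity / rec$peaks$mean_intensity[1],
               c(1, 0.5, 0.2), tolerance = 0.02)
  expect_error(build_msp(b[1:2, ]), "at least 3")
})

test_that("raising the frequency threshold can only shrink the MSP peak set", {
  prof <- quant_profiles()
  b <- simulate_replicates(prof[prof$strain == "DSM 365", ],
                           n_replicates = 8, seed = 5) |>
    preprocess_spectra()
  lo <- build_msp(b, min_frequency = 0.25)
  hi <- build_msp(b, min_frequency = 1.0)
  match_lo <- sapply(hi$peaks$mz, function(m) min(abs(lo$peaks$mz - m)) < 1)
  expect_true(all(match_lo))
  expect_lte(nrow(hi$peaks), nrow(lo$peaks))
  # the generator round trip keeps the DSM 365 marker at 9492 Da
  expect_true(any(abs(lo$peaks$mz - 9492) < 5 & lo$peaks$frequency >= 0.9))
})

test_that("the log-score saturates at self-match and floors at no overlap", {
  rec <- make_record("A", c(3000, 5000, 8000, 11000), c(40, 30, 20, 10))
  self <- tibble::tibble(mz = rec$peaks$mz, intensity = rec$peaks$mean_intensity)
  expect_gte(log_score(self, rec), 2.9)
  # invariance to global intensity scaling of the query
  expect_equal(log_score(dplyr::mutate(self, intensity = intensity * 37), rec),
               log_score(self, rec), tolerance = 1e-12)
  none <- tibble::tibble(mz = c(4000, 6000), intensity = c(1, 1))
  expect_equal(log_score(none, rec), 0)
  expect_error(log_score(self, make_record("x", numeric(0), numeric(0))), "Empty")
})

test_that("the half-matched worked example evaluates to its closed form", {
  rec <- make_record("A", c(3000, 5000, 8000, 11000), c(40, 30, 20, 10))
  # query holds exactly half the MSP peaks, proportional intensities,
  # no unmatched query peaks: score = 3 + log10(1/2)
  half <- tibble::tibble(mz = c(3000, 5000), intensity = c(40, 30))
  expect_equal(log_score(half, rec), 3 + log10(0.5), tolerance = 1e-9)
})

test_that("confidence bands split exactly at the published boundaries", {
  expect_equal(identification_category(c(1.999, 2.000, 1.700, 1.699, 3, 0)),
               c("low_confidence", "high_confidence", "low_confidence",
                 "no_identification", "high_confidence", "no_identification"))
})

test_that("identification ranking is invariant to library composition and order", {
  recs <- list(
    make_record("A", c(3000, 5000, 8000), c(40, 30, 20)),
    make_record("B", c(3100, 5200, 8300), c(10, 30, 50)),
    make_record("C", c(4000, 6000, 9000), c(20, 20, 20))
  )
  q <- tibble::tibble(mz = c(3000, 5000, 8000), intensity = c(40, 30, 20))
  fwd <- identify_spectrum(q, msp_library(recs))
  rev_ <- identify_spectrum(q, msp_library(rev(recs)))
  expect_equal(fwd$record, rev_$record)
  expect_equal(fwd$log_score, rev_$log_score)
  expect_equal(fwd$record[1], "A")
  expect_equal(attr(fwd, "category"), "high_confidence")
  # adding an irrelevant record never changes existing scores
  plus <- identify_spectrum(q, msp_library(c(recs, list(
    make_record("D", c(12000, 13000), c(5, 5))))))
  expect_equal(plus$log_score[match(c("A", "B", "C"), plus$record)],
               fwd$log_score[match(c("A", "B", "C"), fwd$record)])
  expect_error(identify_spectrum(q, msp_library(list())), "Empty")
})
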
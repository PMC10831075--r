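test_that("metric computation guards its denominators", {
  expect_equal(metrics_from_counts(5, 0, 7, 0),
               tibble::tibble(accuracy = 100, sensitivity = 100,
                              specificity = 100))
  expect_error(metrics_from_counts(0, 0, 5, 1), "sensitivity")
  expect_error(metrics_from_counts(5, 1, 0, 0), "specificity")
  expect_error(metrics_from_counts(-1, 1, 1, 1), "non-negative")
})

test_that("QC ranks separable peaks first and is deterministic", {
  m <- simulate_peak_matrix(toy_profiles(), n_replicates = 10, seed = 2)
  qc <- train_qc(m, max_peaks = 1)
  expect_length(qc$peak_masses, 1L)
  expect_equal(predict(qc, m), m$strain)
  expect_identical(train_qc(m, max_peaks = 1), qc)
  expect_error(train_qc(m[m$strain == "A", ]), "two classes")
  expect_error(train_qc(m, max_peaks = 0), "max_peaks")
})

test_that("QC predominantly selects the published quartet on biomarker data", {
  hits <- sum(sapply(1:100, function(i) {
    tr <- simulate_peak_matrix(quant_profiles(), 15, seed = i)
    qc <- train_qc(tr, max_peaks = 4)
    setequal(round(qc$peak_masses), c(2944, 2959, 2874, 3314))
  }))
  expect_gte(hits, 80)
})

test_that("SNN separates well-separated classes and is seed-deterministic", {
  m <- simulate_peak_matrix(toy_profiles(), n_replicates = 10, seed = 4)
  sn <- train_snn(m, seed = 9)
  expect_identical(train_snn(m, seed = 9), sn)
  expect_false(identical(train_snn(m, seed = 10)$prototypes, sn$prototypes))
  expect_equal(predict(sn, m), m$strain)
  te <- simulate_peak_matrix(toy_profiles(), n_replicates = 20, seed = 104)
  expect_equal(predict(sn, te), te$strain)
  expect_error(train_snn(m, n_prototypes = 0), "n_prototypes")
})

test_that("KNN breaks ties deterministically and is exact on its training set", {
  set.seed(1)
  x <- matrix(rnorm(40), 20)
  y <- rep(c("A", "B"), each = 10)
  expect_equal(maldistrain:::knn_predict(x, y, x, 1), y)
  # equidistant neighbours with tied votes: resolved by class order, and
  # stable across repeated calls
  tr <- matrix(c(0, 1, 0, -1), 2, byrow = TRUE)
  p1 <- maldistrain:::knn_predict(tr, c("B", "A"), matrix(c(0, 0), 1), 1)
  expect_equal(p1, "B")
  expect_equal(maldistrain:::knn_predict(tr, c("B", "A"),
                                         matrix(c(0, 0), 1), 1), p1)
})

test_that("the GA improves monotonically, honours bounds and recovers planted features", {
  m <- simulate_peak_matrix(quant_profiles(), 15, seed = 3)
  expect_error(train_ga_knn(m, k = 2), "odd")
  g0 <- train_ga_knn(m, k = 1, n_generations = 0, seed = 5)
  expect_length(g0$fitness_history, 1L)
  g <- train_ga_knn(m, k = 1, n_generations = 8, max_peaks = 3, seed = 5)
  expect_true(all(diff(g$fitness_history) >= 0))
  expect_lte(length(g$peak_masses), 3L)
  expect_identical(train_ga_knn(m, k = 1, n_generations = 8, max_peaks = 3,
                                seed = 5), g)

  set.seed(9)
  n <- 30
  lab <- rep(c("A", "B"), each = n / 2)
  x <- cbind(matrix(rnorm(n * 20), n), c(rnorm(n / 2, 0), rnorm(n / 2, 4)))
  masses <- 2000 + (1:21) * 100
  colnames(x) <- sprintf("mz_%d.00", masses)
  pm <- maldistrain:::new_peak_matrix(
    dplyr::bind_cols(tibble::tibble(strain = lab, replicate = seq_len(n)),
                     tibble::as_tibble(x)), masses)
  hits <- sum(sapply(1:20, function(s) {
    gg <- train_ga_knn(pm, k = 1, max_peaks = 5, n_generations = 15, seed = s)
    4100 %in% round(gg$peak_masses)
  }))
  expect_gte(hits, 19)
})

test_that("external validation produces one-vs-rest rows with consistent counts", {
  tr <- simulate_peak_matrix(quant_profiles(), 15, seed = 12)
  te <- simulate_peak_matrix(quant_profiles(), c(21, 20, 20), seed = 10012)
  qc <- train_qc(tr)
  rep_ <- external_validate(qc, te)
  expect_equal(rep_$class, unique(tr$strain))
  expect_equal(rep_$tp + rep_$fn, c(21, 20, 20))
  expect_equal(rep_$tn + rep_$fp, 61 - c(21, 20, 20))
  expect_error(external_validate(qc, te[0, ]), "Empty")
  # unalignable masses are reported
  off <- te
  attr(off, "peak_centers") <- peak_centers(te) + 500
  expect_error(external_validate(qc, off), "lacks peaks")
})

test_that("a 14-of-20 partially sensitive class reproduces the printed row", {
  # directly the published arithmetic: tp 14, fn 6, tn 41, fp 0
  row <- metrics_from_counts(14, 6, 41, 0)
  expect_equal(row$accuracy, 90.16)
  expect_equal(row$sensitivity, 70)
  expect_equal(row$specificity, 100)
  # and through external_validate on constructed predictions: class B test
  # points partially mimic class A so a nearest-centroid model misses 6
  tr <- simulate_peak_matrix(toy_profiles(), 10, seed = 6)
  qc <- train_qc(tr, max_peaks = 2)
  teA <- simulate_peak_matrix(toy_profiles(), c(21, 0), seed = 7)
  teB_good <- simulate_peak_matrix(toy_profiles(), c(0, 14), seed = 8)
  teB_bad <- simulate_peak_matrix(toy_profiles(), c(6, 0), seed = 9)
  teB_bad$strain <- "B"  # truly labelled B, but A-shaped
  te <- dplyr::bind_rows(teA, teB_good, teB_bad)
  te <- maldistrain:::new_peak_matrix(te, peak_centers(tr))
  rep_ <- external_validate(qc, te)
  b <- rep_[rep_$class == "B", ]
  expect_equal(c(b$tp, b$fn, b$fp), c(14, 6, 0))
  expect_equal(b$accuracy, round(100 * 35 / 41, 2))
  expect_equal(b$sensitivity, 70)
  expect_equal(b$specificity, 100)
})

test_that("classifier tidiers expose peaks and fit summaries", {
  m <- simulate_peak_matrix(quant_profiles(), 15, seed = 2)
  qc <- train_qc(m)
  td <- tidy(qc)
  expect_equal(nrow(td), 4L)
  expect_true(all(c("peak_mass", "p_value", "weight") %in% names(td)))
  g <- glance(train_ga_knn(m, k = 1, n_generations = 2, seed = 1))
  expect_equal(g$kind, "ga_knn")
  expect_true(g$cv_accuracy >= 0 && g$cv_accuracy <= 1)
})
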
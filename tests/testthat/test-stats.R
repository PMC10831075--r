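test_that("the Anderson-Darling test holds its size and detects outliers", {
  set.seed(42)
  rej <- mean(replicate(200, ad_normality_p(rnorm(15, 10, 2)) <= 0.05))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
  spiked <- c(rep(1, 14) + rnorm(14, 0, 0.01), 1000)
  expect_lt(ad_normality_p(spiked), 0.05)
  expect_error(ad_normality_p(rnorm(4)), "at least 5")
  expect_error(ad_statistic(rep(2, 10)), "variance")
})

test_that("the AD statistic matches direct order-statistic evaluation and nortest", {
  set.seed(7)
  x10 <- rnorm(10, 5, 2)
  expect_equal(ad_statistic(x10), brute_ad_a2(x10), tolerance = 1e-10)
  skip_if_not_installed("nortest")
  for (n in c(8, 12, 30)) {
    x <- rnorm(n)
    ref <- nortest::ad.test(x)
    expect_equal(ad_statistic(x), unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ad_normality_p(x), ref$p.value, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis agrees with the rank-sum brute force", {
  g <- rep(1:3, each = 3)
  v <- 1:9
  kw <- wkw_test(v, g)
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$statistic, brute_kruskal_h(v, g), tolerance = 1e-12)

  set.seed(11)
  for (rep in 1:20) {
    k <- sample(3:4, 1)
    sizes <- sample(2:4, k, replace = TRUE)
    n <- sum(sizes)
    if (n > 12) next
    g <- rep(seq_len(k), sizes)
    v <- sample(1:6, n, replace = TRUE)  # forces ties
    if (all(v == v[1])) next
    kw <- wkw_test(v, g)
    expect_equal(kw$statistic, brute_kruskal_h(v, g), tolerance = 1e-10)
    expect_equal(kw$statistic, unname(kruskal.test(v, g)$statistic),
                 tolerance = 1e-12)
  }

  same <- rep(c(1, 2, 3), 3)
  g3 <- rep(1:3, each = 3)
  expect_equal(wkw_test(rep(5, 9), g3)$statistic, 0)
  expect_equal(one_way_anova(rep(5, 9), g3)$statistic, 0)
})

test_that("well-separated biomarker groups give vanishing rank-test p-values", {
  # ATCC 842 vs DSM 292 at 2944 Da: Normal(27.55, 6.31) vs Normal(0.93, 0.16)
  hits <- sum(sapply(1:100, function(s) {
    set.seed(s)
    a <- rnorm(15, 27.55, 6.31)
    b <- rnorm(15, 0.93, 0.16)
    wkw_test(c(a, b), rep(1:2, each = 15))$p_value < 1e-4
  }))
  expect_gte(hits, 99)
})

test_that("log2 fold changes are antisymmetric and match worked arithmetic", {
  expect_equal(log2_fold_change(5, 5, 1e-6), 0)
  expect_equal(log2_fold_change(9.39, 0.81, 1e-9), log2(9.39 / 0.81),
               tolerance = 1e-6)
  expect_equal(log2(9.39 / 0.81), 3.535, tolerance = 5e-4)
  expect_equal(log2_fold_change(4.03, 1.23, 1e-9), 1.712, tolerance = 5e-4)
  set.seed(2)
  for (rep in 1:10) {
    a <- runif(1, 0, 30); b <- runif(1, 0, 30); f <- runif(1, 1e-8, 1)
    expect_equal(log2_fold_change(a, b, f), -log2_fold_change(b, a, f),
                 tolerance = 1e-12)
  }
  expect_error(log2_fold_change(-1, 2, 1), "non-negative")
  expect_error(log2_fold_change(1, 2, 0), "positive")
})

test_that("the AD gate routes each peak to exactly one location test", {
  m <- simulate_peak_matrix(quant_profiles(), n_replicates = 15, seed = 5)
  tab <- select_characteristic_peaks(m)
  expect_equal(nrow(tab), 7L)
  expect_true(all(tab$test %in% c("anova", "kruskal-wallis", "wilcoxon")))
  # gated consistency: wkw iff AD rejected (or AD undefined)
  expect_equal(tab$test != "anova", is.na(tab$p_ad) | tab$p_ad <= 0.05)
  # log2fc columns are antisymmetric
  expect_equal(tab$`log2fc_ATCC 842_vs_DSM 292`,
               -tab$`log2fc_DSM 292_vs_ATCC 842`)
  # alpha = 0 selects nothing
  expect_false(any(select_characteristic_peaks(m, alpha = 0)$selected))
  # global gate applies one family everywhere
  tabg <- select_characteristic_peaks(m, gate = "global")
  expect_length(unique(tabg$test == "anova"), 1L)
  one_class <- m[m$strain == "DSM 365", ]
  expect_error(select_characteristic_peaks(one_class), "two classes")
})

test_that("null peaks are selected at close to the nominal rate", {
  # identical distributions in all classes: selection rate per peak <= 10%
  means <- matrix(5, 3, 7, dimnames = list(c("A", "B", "C"), NULL))
  sds <- matrix(1, 3, 7)
  sel <- matrix(FALSE, 100, 7)
  for (i in 1:100) {
    m <- matrix_from_normals(means, sds, 15, 2000 + (1:7) * 500, seed = 3000 + i)
    sel[i, ] <- select_characteristic_peaks(m)$selected
  }
  expect_true(all(colMeans(sel) <= 0.10))
})

test_that("PCA conserves variance and separates the three strains", {
  m <- simulate_peak_matrix(quant_profiles(), n_replicates = 15, seed = 8)
  # rank-1 input: PC1 explains everything
  v <- intensity_values(m)
  rank1 <- v[, 1, drop = FALSE] %*% t(c(1, 2, 3))
  colnames(rank1) <- sprintf("mz_%d.00", c(3000, 4000, 5000))
  m1 <- maldistrain:::new_peak_matrix(
    dplyr::bind_cols(m[c("strain", "replicate")], tibble::as_tibble(rank1)),
    c(3000, 4000, 5000))
  p1 <- run_pca(m1, n_components = 2)
  expect_equal(p1$explained_variance_fraction[1], 1, tolerance = 1e-9)
  # full-rank fractions sum to one
  pf <- run_pca(m, n_components = 7)
  expect_equal(sum(pf$all_variance_fractions), 1, tolerance = 1e-12)
  expect_true(all(diff(pf$all_variance_fractions) <= 1e-12))
  expect_error(run_pca(m, n_components = 10), "n_components")

  # score-space separation: disjoint class hulls in (PC1, PC2)
  ok <- sum(sapply(1:100, function(i) {
    mi <- simulate_peak_matrix(quant_profiles(), n_replicates = 15,
                               seed = 7000 + i)
    sc <- run_pca(mi, n_components = 2)$scores
    xy <- as.matrix(sc[c("PC1", "PC2")])
    cl <- split(seq_len(nrow(xy)), sc$strain)
    all(hulls_disjoint(xy[cl[[1]], ], xy[cl[[2]], ]),
        hulls_disjoint(xy[cl[[1]], ], xy[cl[[3]], ]),
        hulls_disjoint(xy[cl[[2]], ], xy[cl[[3]], ]))
  }))
  expect_gte(ok, 95)
})
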
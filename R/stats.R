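# Discriminant peak statistics: Anderson-Darling-gated ANOVA / Wilcoxon-
# Kruskal-Wallis selection, log2 fold changes, and PCA.

#' Anderson-Darling composite normality test
#'
#' Tests the composite hypothesis that a sample is Normal with unspecified
#' mean and variance. The statistic is the standard order-statistic sum with
#' estimated parameters; the small-sample adjustment
#' `A* = A^2 (1 + 0.75/n + 2.25/n^2)` and the published piecewise-exponential
#' p-value approximation (Stephens / D'Agostino) are applied.
#'
#' @param x Numeric sample, `n >= 5`.
#' @return For `ad_statistic()`, the unadjusted statistic `A^2`; for
#'   `ad_normality_p()`, the p-value.
#' @export
ad_normality_p <- function(x) {
  a2 <- ad_statistic(x)
  n <- length(x)
  a <- a2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (a < 0.2) {
    1 - exp(-13.436 + 101.14 * a - 223.73 * a^2)
  } else if (a < 0.34) {
    1 - exp(-8.318 + 42.796 * a - 59.938 * a^2)
  } else if (a < 0.6) {
    exp(0.9177 - 4.279 * a - 1.38 * a^2)
  } else if (a < 10) {
    exp(1.2937 - 5.709 * a + 0.0186 * a^2)
  } else {
    0
  }
  min(max(p, 0), 1)
}

#' @rdname ad_normality_p
#' @export
ad_statistic <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 5L) abort("Anderson-Darling test needs at least 5 observations.")
  s <- sd(x)
  if (!is.finite(s) || s <= 0) abort("Anderson-Darling test needs non-zero variance.")
  z <- pnorm((x - mean(x)) / s)
  eps <- 1e-17
  z <- pmin(pmax(z, eps), 1 - eps)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(z) + log(1 - rev(z))))
}

#' Wilcoxon / Kruskal-Wallis location test across groups
#'
#' Two groups are compared by the Wilcoxon rank-sum test (normal
#' approximation, no continuity correction); three or more by the
#' Kruskal-Wallis test with mid-ranks, tie correction and a chi-square
#' reference on k - 1 degrees of freedom. Completely constant data give
#' statistic 0 and p 1.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length.
#' @return A list with `statistic`, `p_value` and `method`.
#' @export
wkw_test <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) abort("Need at least two groups.")
  if (any(table(groups) < 2L)) abort("Each group needs at least two observations.")
  if (all(values == values[1L])) {
    return(list(statistic = 0, p_value = 1,
                method = if (nlevels(groups) == 2L) "wilcoxon" else "kruskal-wallis"))
  }
  if (nlevels(groups) == 2L) {
    lv <- levels(groups)
    ht <- suppressWarnings(
      wilcox.test(values[groups == lv[1L]], values[groups == lv[2L]],
                  exact = FALSE, correct = FALSE)
    )
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "wilcoxon")
  } else {
    ht <- kruskal.test(values, groups)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "kruskal-wallis")
  }
}

#' One-way analysis of variance
#'
#' Classic equal-variance one-way F test. Completely constant data give
#' F 0 and p 1.
#'
#' @inheritParams wkw_test
#' @return A list with `statistic`, `p_value` and `method`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) abort("Need at least two groups.")
  if (all(values == values[1L])) {
    return(list(statistic = 0, p_value = 1, method = "anova"))
  }
  ht <- oneway.test(values ~ groups, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value, method = "anova")
}

#' log2 fold change between two mean intensities
#'
#' `log2((a + floor) / (b + floor))`; the floor guards absent peaks against
#' division by zero. Antisymmetric in its arguments and exactly zero at
#' equality.
#'
#' @param mean_a,mean_b Non-negative mean intensities.
#' @param floor Positive stabilising offset.
#' @return The dimensionless log2 ratio.
#' @export
log2_fold_change <- function(mean_a, mean_b, floor = 1e-6) {
  if (any(mean_a < 0) || any(mean_b < 0)) abort("Means must be non-negative.")
  if (floor <= 0) abort("`floor` must be positive.")
  log2((mean_a + floor) / (mean_b + floor))
}

#' Select characteristic (discriminant) peaks by the gated testing scheme
#'
#' Per peak, an Anderson-Darling normality test on the pooled within-class
#' centred residuals decides the location test: if normality is *not*
#' rejected (`p_ad > alpha`) a one-way ANOVA supplies the selection p-value,
#' otherwise the Wilcoxon / Kruskal-Wallis test does. Peaks whose gated
#' p-value is at most `alpha` are flagged `selected`. With
#' `gate = "global"`, a single switch — the worst-case (minimum) AD p across
#' peaks — chooses one test family for every peak.
#'
#' @param m A peak-matrix tibble with a `strain` column and at least two
#'   classes, two replicates each.
#' @param alpha Significance cut-off (default 0.05), applied to both the gate
#'   and the selection.
#' @param gate `"per_peak"` (default) or `"global"`.
#' @param p_adjust `"none"` (default, a raw cut-off) or `"BH"` for a
#'   Benjamini-Hochberg adjusted selection.
#' @param fc_floor Fold-change floor; default `1e-6 *` the matrix maximum.
#' @return A discriminant-peak tibble: `mass`, `p_ad`, `test`, `p_value`,
#'   `selected`, per-class `mean_<class>` / `sd_<class>` columns, and a
#'   `log2fc_<A>_vs_<B>` column per ordered class pair.
#' @export
select_characteristic_peaks <- function(m, alpha = 0.05,
                                        gate = c("per_peak", "global"),
                                        p_adjust = c("none", "BH"),
                                        fc_floor = NULL) {
  gate <- match.arg(gate)
  p_adjust <- match.arg(p_adjust)
  if (!("strain" %in% names(m))) abort("`m` must carry a `strain` column.")
  classes <- unique(m$strain)
  if (length(classes) < 2L) abort("Need at least two classes.")
  if (any(table(m$strain) < 2L)) abort("Each class needs at least two replicates.")
  vals <- intensity_values(m)
  centres <- peak_centers(m)
  if (is.null(fc_floor)) fc_floor <- max(vals) * 1e-6
  groups <- as.factor(m$strain)

  per_peak <- purrr::map(seq_len(ncol(vals)), function(j) {
    x <- vals[, j]
    resid <- x - ave(x, groups)
    p_ad <- if (sd(resid) <= 0) NA_real_ else ad_normality_p(resid)
    list(x = x, p_ad = p_ad)
  })
  ad_ps <- purrr::map_dbl(per_peak, "p_ad")
  use_wkw <- if (gate == "global") {
    rep(min(ad_ps, na.rm = TRUE) <= alpha || anyNA(ad_ps), length(ad_ps))
  } else {
    is.na(ad_ps) | ad_ps <= alpha
  }

  rows <- purrr::map(seq_along(per_peak), function(j) {
    x <- per_peak[[j]]$x
    ht <- if (use_wkw[j]) wkw_test(x, groups) else one_way_anova(x, groups)
    stats_by_class <- purrr::map(classes, function(cl) {
      xi <- x[m$strain == cl]
      c(mean(xi), sd(xi))
    })
    row <- tibble(mass = centres[j], p_ad = per_peak[[j]]$p_ad,
                  test = ht$method, statistic = ht$statistic,
                  p_value = ht$p_value)
    for (k in seq_along(classes)) {
      row[[paste0("mean_", classes[k])]] <- stats_by_class[[k]][1L]
      row[[paste0("sd_", classes[k])]] <- stats_by_class[[k]][2L]
    }
    for (a in seq_along(classes)) {
      for (b in seq_along(classes)) {
        if (a == b) next
        row[[sprintf("log2fc_%s_vs_%s", classes[a], classes[b])]] <-
          log2_fold_change(stats_by_class[[a]][1L], stats_by_class[[b]][1L],
                           floor = fc_floor)
      }
    }
    row
  }) |> bind_rows()

  p_sel <- if (p_adjust == "BH") p.adjust(rows$p_value, "BH") else rows$p_value
  rows$selected <- p_sel <= alpha
  rows
}

#' Principal component analysis of a peak-intensity matrix
#'
#' Centred (optionally scaled) PCA of the spectra x peaks intensities.
#'
#' @inheritParams select_characteristic_peaks
#' @param n_components Components to retain (at most `min(dim)`).
#' @param scale. Scale columns to unit variance first? Default `FALSE`
#'   (analysis on raw intensities).
#' @return An object of class `maldi_pca`: list with `scores` (tibble with
#'   `strain` and `PC` columns), `loadings` (tibble with `mass` and `PC`
#'   columns) and `explained_variance_fraction`.
#' @export
run_pca <- function(m, n_components = 2, scale. = FALSE) {
  vals <- intensity_values(m)
  if (nrow(vals) < 2L) abort("PCA needs more than one spectrum.")
  if (n_components > min(dim(vals))) {
    abort("`n_components` exceeds the matrix rank bound.")
  }
  fit <- prcomp(vals, center = TRUE, scale. = scale.)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  k <- seq_len(n_components)
  scores <- as_tibble(fit$x[, k, drop = FALSE])
  if ("strain" %in% names(m)) scores <- bind_cols(m["strain"], scores)
  loadings <- bind_cols(tibble(mass = peak_centers(m)),
                        as_tibble(fit$rotation[, k, drop = FALSE]))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = expl[k],
                 all_variance_fractions = expl),
            class = "maldi_pca")
}

#' @export
print.maldi_pca <- function(x, ...) {
  cat("PCA of peak intensities:",
      sprintf("PC%d = %.1f%%", seq_along(x$explained_variance_fraction),
              100 * x$explained_variance_fraction), "\n")
  invisible(x)
}
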
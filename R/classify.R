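# Classifier families: p-value-weighted quick classifier (QC), supervised
# prototype network (SNN, learning-vector-quantisation style), and
# genetic-algorithm KNN (GA_KNN), with external one-vs-rest validation.

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = (tp + tn) / (tp + tn + fp + fn)`, `sensitivity = tp / (tp + fn)`,
#' `specificity = tn / (tn + fp)`, each times 100 and reported to two
#' decimals. A zero denominator is an error naming the undefined metric.
#'
#' @param tp,fn,tn,fp Non-negative integer counts (vectorised).
#' @return A tibble with columns `accuracy`, `sensitivity`, `specificity` (%).
#' @export
#' @examples
#' metrics_from_counts(tp = 14, fn = 6, tn = 41, fp = 0)
metrics_from_counts <- function(tp, fn, tn, fp) {
  counts <- cbind(tp, fn, tn, fp)
  if (any(counts < 0)) abort("Confusion counts must be non-negative.")
  if (any(tp + tn + fp + fn == 0)) abort("accuracy is undefined: no test spectra.")
  if (any(tp + fn == 0)) abort("sensitivity is undefined: no true-class spectra.")
  if (any(tn + fp == 0)) abort("specificity is undefined: no non-class spectra.")
  tibble(
    accuracy = round(100 * (tp + tn) / (tp + tn + fp + fn), 2),
    sensitivity = round(100 * tp / (tp + fn), 2),
    specificity = round(100 * tn / (tn + fp), 2)
  )
}

# ---- shared internals -------------------------------------------------------

check_training_matrix <- function(m) {
  if (!("strain" %in% names(m))) abort("Training matrix needs a `strain` column.")
  if (length(unique(m$strain)) < 2L) abort("Training needs at least two classes.")
  invisible(m)
}

standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[scl <= 0] <- 1
  list(center = ctr, scale = scl,
       apply = function(z) sweep(sweep(z, 2L, ctr), 2L, scl, "/"))
}

# Match the model's peak masses to the columns of a test matrix within a ppm
# tolerance; unalignable masses are an error listing what is missing.
align_columns <- function(masses, m, tol_ppm = 600) {
  centres <- peak_centers(m)
  idx <- purrr::map_int(masses, function(mass) {
    d <- abs(centres - mass) / mass * 1e6
    j <- which.min(d)
    if (d[j] <= tol_ppm) j else NA_integer_
  })
  if (anyNA(idx)) {
    abort(sprintf("Test matrix lacks peaks at: %s Da",
                  paste(round(masses[is.na(idx)], 1), collapse = ", ")))
  }
  idx
}

# Deterministic KNN with the documented tie-breaks: majority vote among the k
# nearest; ties broken by smallest mean distance within the k nearest, then
# by class order.
knn_predict <- function(train_x, train_y, test_x, k) {
  classes <- unique(train_y)
  d2 <- outer(rowSums(test_x^2), rep(1, nrow(train_x))) +
    outer(rep(1, nrow(test_x)), rowSums(train_x^2)) -
    2 * tcrossprod(test_x, train_x)
  apply_row <- function(i) {
    ord <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]
    votes <- table(factor(train_y[ord], levels = classes))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      mean_d <- purrr::map_dbl(top, ~ mean(d2[i, ord[train_y[ord] == .x]]))
      top <- top[order(mean_d, match(top, classes))]
    }
    top[1L]
  }
  purrr::map_chr(seq_len(nrow(test_x)), apply_row)
}

new_classifier <- function(.kind, ...) {
  structure(list(kind = .kind, ...),
            class = c(paste0(.kind, "_model"), "maldi_classifier"))
}

#' @export
print.maldi_classifier <- function(x, ...) {
  cat(sprintf("<%s classifier> classes: %s | peaks (Da): %s\n",
              toupper(x$kind), paste(x$classes, collapse = ", "),
              paste(round(x$peak_masses, 1), collapse = ", ")))
  invisible(x)
}

# ---- Quick Classifier -------------------------------------------------------

#' Train the p-value-sorted Quick Classifier (QC)
#'
#' Peaks are ranked by ascending Wilcoxon/Kruskal-Wallis p-value and the top
#' `max_peaks` retained. The model stores each retained peak's per-class mean
#' and standard deviation plus a weight proportional to `-log10(p)`
#' (normalised to sum 1); prediction assigns the class minimising the
#' weighted standardised distance `sum_j w_j ((x_j - mu_cj) / sigma_cj)^2`.
#' Deterministic given its input.
#'
#' @param m Training peak matrix (with `strain` labels).
#' @param max_peaks Number of peaks retained (default 4).
#' @return A `maldi_classifier` of kind `"qc"`.
#' @export
train_qc <- function(m, max_peaks = 4) {
  check_training_matrix(m)
  if (max_peaks < 1) abort("`max_peaks` must be at least 1.")
  vals <- intensity_values(m)
  centres <- peak_centers(m)
  classes <- unique(m$strain)
  tests <- purrr::map(seq_len(ncol(vals)), ~ wkw_test(vals[, .x], m$strain))
  p <- purrr::map_dbl(tests, "p_value")
  stat <- purrr::map_dbl(tests, "statistic")
  ord <- order(p, -stat, centres)
  keep <- ord[seq_len(min(max_peaks, length(ord)))]
  w <- -log10(pmax(p[keep], 1e-300))
  if (sum(w) <= 0) w <- rep(1, length(w))
  w <- w / sum(w)
  sd_floor <- 1e-8 * max(abs(vals))
  mu <- purrr::map(classes, function(cl) colMeans(vals[m$strain == cl, keep, drop = FALSE]))
  sg <- purrr::map(classes, function(cl) {
    s <- apply(vals[m$strain == cl, keep, drop = FALSE], 2L, sd)
    pmax(s, sd_floor)
  })
  new_classifier("qc",
                 classes = classes,
                 peak_masses = centres[keep],
                 p_values = p[keep],
                 weights = w,
                 class_means = setNames(mu, classes),
                 class_sds = setNames(sg, classes))
}

#' @export
predict.qc_model <- function(object, newdata, tol_ppm = 600, ...) {
  idx <- align_columns(object$peak_masses, newdata, tol_ppm)
  x <- intensity_values(newdata)[, idx, drop = FALSE]
  d <- purrr::map(object$classes, function(cl) {
    mu <- object$class_means[[cl]]
    sg <- object$class_sds[[cl]]
    colSums(object$weights * ((t(x) - mu) / sg)^2)
  })
  d <- do.call(cbind, d)
  object$classes[apply(d, 1L, which.min)]
}

# ---- Supervised prototype network (SNN) ------------------------------------

# Distance of rows of x to a Gaussian prototype: dimension-wise standardised
# squared distance plus the 2*sum(log sd) normalising term of a diagonal
# Gaussian log-likelihood.
proto_dist <- function(x, mu, sd) {
  colSums(((t(x) - mu) / sd)^2) + 2 * sum(log(sd))
}

# Leave-one-out accuracy and mean margin of the one-prototype-per-class
# Gaussian classifier on columns `cols`; class statistics are recomputed
# without the held-out point via closed-form downdates.
loo_gaussian_accuracy <- function(vals, y, classes, cols, sd_floor) {
  x <- vals[, cols, drop = FALSE]
  n <- nrow(x)
  d <- matrix(NA_real_, n, length(classes))
  for (ci in seq_along(classes)) {
    idx <- which(y == classes[ci])
    nc <- length(idx)
    mu <- colMeans(x[idx, , drop = FALSE])
    ss <- colSums((x[idx, , drop = FALSE] - rep(mu, each = nc))^2)
    sd_full <- pmax(sqrt(ss / (nc - 1L)), sd_floor)
    out <- setdiff(seq_len(n), idx)
    d[out, ci] <- proto_dist(x[out, , drop = FALSE], mu, sd_full)
    for (i in idx) {
      mu_i <- (mu * nc - x[i, ]) / (nc - 1L)
      ss_i <- ss - (nc / (nc - 1L)) * (x[i, ] - mu)^2
      sd_i <- pmax(sqrt(pmax(ss_i, 0) / max(nc - 2L, 1L)), sd_floor)
      d[i, ci] <- proto_dist(x[i, , drop = FALSE], mu_i, sd_i)
    }
  }
  own <- match(y, classes)
  d_own <- d[cbind(seq_len(n), own)]
  d_other <- purrr::map_dbl(seq_len(n), ~ min(d[.x, -own[.x]]))
  list(accuracy = mean(d_own < d_other &
                         d_own == apply(d, 1L, min)),
       margin = mean(d_other - d_own))
}

#' Train the supervised prototype network (SNN)
#'
#' A prototype classifier in the learning-vector-quantisation family, with
#' Gaussian receptive fields: each prototype carries a position and
#' per-dimension widths (the class standard deviations), and distance is the
#' width-standardised squared distance plus the Gaussian `2 sum(log sd)`
#' term, so a class that is tight on a marker peak claims it strongly.
#' Peaks enter by greedy forward selection maximising leave-one-out accuracy
#' of the one-prototype-per-class model, ties broken by the larger
#' classification margin, up to `max_peaks` (default 3 — in practice the
#' selection pairs one marker peak per strain). Prototype positions
#' (class centroids, or seeded k-means centres when `n_prototypes > 1`) are
#' then refined by LVQ1 updates. Prediction is the class of the nearest
#' prototype. Seed-deterministic.
#'
#' @inheritParams train_qc
#' @param max_peaks Peaks retained by greedy selection (default 3).
#' @param n_prototypes Prototypes per class (default 1).
#' @param epochs LVQ1 refinement epochs (default 10).
#' @param learning_rate Initial LVQ1 learning rate, decayed linearly to zero.
#' @param seed Integer seed.
#' @return A `maldi_classifier` of kind `"snn"`.
#' @export
train_snn <- function(m, max_peaks = 3, n_prototypes = 1, epochs = 10,
                      learning_rate = 0.02, seed = 1) {
  check_training_matrix(m)
  if (n_prototypes < 1) abort("`n_prototypes` must be at least 1.")
  vals <- intensity_values(m)
  centres <- peak_centers(m)
  classes <- unique(m$strain)
  y <- m$strain
  sd_floor <- 1e-8 * max(abs(vals), 1e-12)

  selected <- integer(0)
  while (length(selected) < min(max_peaks, ncol(vals))) {
    cand <- setdiff(seq_len(ncol(vals)), selected)
    scored <- purrr::map(cand, function(j) {
      loo_gaussian_accuracy(vals, y, classes, c(selected, j), sd_floor)
    })
    acc <- purrr::map_dbl(scored, "accuracy")
    mar <- purrr::map_dbl(scored, "margin")
    selected <- c(selected, cand[order(-acc, -mar, cand)][1L])
  }

  xs <- vals[, selected, drop = FALSE]
  withr::with_seed(as.integer(seed), {
    protos <- purrr::map(classes, function(cl) {
      xc <- xs[y == cl, , drop = FALSE]
      sd_c <- pmax(apply(xc, 2L, sd), sd_floor)
      mus <- if (n_prototypes == 1L) {
        matrix(colMeans(xc), nrow = 1L)
      } else {
        stats::kmeans(xc, centers = min(n_prototypes, nrow(xc)), nstart = 5)$centers
      }
      list(mu = mus, sd = sd_c)
    })
    w <- do.call(rbind, purrr::map(protos, "mu"))
    w_sd <- do.call(rbind, purrr::map(seq_along(protos), function(i) {
      matrix(protos[[i]]$sd, nrow(protos[[i]]$mu), ncol(xs), byrow = TRUE)
    }))
    w_class <- rep(classes, purrr::map_int(protos, ~ nrow(.x$mu)))
    n <- nrow(xs)
    total <- max(epochs * n, 1L)
    t <- 0L
    for (e in seq_len(epochs)) {
      for (i in sample.int(n)) {
        t <- t + 1L
        lr <- learning_rate * (1 - (t - 1L) / total)
        d <- purrr::map_dbl(seq_len(nrow(w)), function(p) {
          proto_dist(xs[i, , drop = FALSE], w[p, ], w_sd[p, ])
        })
        j <- which.min(d)
        dir <- if (w_class[j] == y[i]) 1 else -1
        w[j, ] <- w[j, ] + dir * lr * (xs[i, ] - w[j, ])
      }
    }
    new_classifier("snn",
                   classes = classes,
                   peak_masses = centres[selected],
                   prototypes = w,
                   prototype_sd = w_sd,
                   prototype_class = w_class,
                   seed = as.integer(seed))
  })
}

#' @export
predict.snn_model <- function(object, newdata, tol_ppm = 600, ...) {
  idx <- align_columns(object$peak_masses, newdata, tol_ppm)
  x <- intensity_values(newdata)[, idx, drop = FALSE]
  w <- object$prototypes
  purrr::map_chr(seq_len(nrow(x)), function(i) {
    d <- purrr::map_dbl(seq_len(nrow(w)), function(p) {
      proto_dist(x[i, , drop = FALSE], w[p, ], object$prototype_sd[p, ])
    })
    object$prototype_class[which.min(d)]
  })
}

# ---- Genetic-algorithm KNN --------------------------------------------------

#' Train the genetic-algorithm KNN classifier (GA_KNN)
#'
#' A genetic algorithm over peak subsets (bit-mask chromosomes with at most
#' `max_peaks` set bits) maximises the internal cross-validated accuracy of a
#' K-nearest-neighbour classifier; exactly `n_generations` generations are
#' run (0 returns the best of the random initial population). Tournament
#' selection, uniform crossover, per-bit mutation and single elitism; the
#' elite guarantees a non-decreasing best fitness. Seed-deterministic.
#'
#' @inheritParams train_qc
#' @param k Neighbour count; odd (1, 3, 5 or 7).
#' @param max_peaks Maximal peaks in the model (default 30).
#' @param n_generations Generations to run (default 50).
#' @param pop_size Population size (default 64).
#' @param crossover_p Per-pair uniform-crossover probability (default 0.7).
#' @param mutation_p Per-bit mutation probability; default `1 /` number of
#'   peaks.
#' @param tournament Tournament size (default 3).
#' @param n_folds Internal cross-validation folds for the fitness (default 5).
#' @param seed Integer seed.
#' @return A `maldi_classifier` of kind `"ga_knn"` carrying the selected
#'   subset, the standardised training data and the fitness history.
#' @export
train_ga_knn <- function(m, k = 1, max_peaks = 30, n_generations = 50,
                         pop_size = 64, crossover_p = 0.7, mutation_p = NULL,
                         tournament = 3, n_folds = 5, seed = 1) {
  check_training_matrix(m)
  if (k %% 2 == 0) abort("`k` must be odd (even k is tie-prone).")
  vals <- intensity_values(m)
  centres <- peak_centers(m)
  classes <- unique(m$strain)
  y <- m$strain
  std <- standardizer(vals)
  z <- std$apply(vals)
  p <- ncol(z)
  if (is.null(mutation_p)) mutation_p <- 1 / p

  withr::with_seed(as.integer(seed), {
    folds <- unlist(purrr::map(classes, function(cl) {
      idx <- which(y == cl)
      setNames(rep_len(seq_len(n_folds), length(idx))[sample.int(length(idx))], idx)
    }))
    fold_of <- integer(length(y))
    fold_of[as.integer(names(folds))] <- folds

    cache <- new.env(parent = emptyenv())
    fitness <- function(bits) {
      key <- paste(which(bits), collapse = ",")
      if (!is.null(cache[[key]])) return(cache[[key]])
      cols <- which(bits)
      acc <- mean(purrr::map_dbl(seq_len(n_folds), function(f) {
        tr <- fold_of != f
        if (!any(!tr)) return(NA_real_)
        pred <- knn_predict(z[tr, cols, drop = FALSE], y[tr],
                            z[!tr, cols, drop = FALSE], k)
        mean(pred == y[!tr])
      }), na.rm = TRUE)
      cache[[key]] <- acc
      acc
    }

    repair <- function(bits) {
      on <- which(bits)
      if (length(on) > max_peaks) {
        bits[sample(on, length(on) - max_peaks)] <- FALSE
      } else if (!length(on)) {
        bits[sample.int(p, 1L)] <- TRUE
      }
      bits
    }

    pop <- purrr::map(seq_len(pop_size), function(i) {
      repair(runif(p) < min(max_peaks / p, 0.5))
    })
    fit <- purrr::map_dbl(pop, fitness)
    history <- max(fit)

    for (g in seq_len(n_generations)) {
      pick <- function() {
        cand <- sample.int(pop_size, tournament, replace = TRUE)
        cand[which.max(fit[cand])]
      }
      elite <- pop[[which.max(fit)]]
      nxt <- vector("list", pop_size)
      nxt[[1L]] <- elite
      i <- 2L
      while (i <= pop_size) {
        a <- pop[[pick()]]
        b <- pop[[pick()]]
        if (runif(1) < crossover_p) {
          mask <- runif(p) < 0.5
          tmp <- a
          a[mask] <- b[mask]
          b[mask] <- tmp[mask]
        }
        for (child in list(a, b)) {
          if (i > pop_size) break
          flip <- runif(p) < mutation_p
          child[flip] <- !child[flip]
          nxt[[i]] <- repair(child)
          i <- i + 1L
        }
      }
      pop <- nxt
      fit <- purrr::map_dbl(pop, fitness)
      history <- c(history, max(fit))
    }

    best <- pop[[which.max(fit)]]
    new_classifier("ga_knn",
                   classes = classes,
                   peak_masses = centres[which(best)],
                   k = k,
                   train_z = z[, which(best), drop = FALSE],
                   train_y = y,
                   center = std$center[which(best)],
                   scale = std$scale[which(best)],
                   cv_accuracy = max(fit),
                   fitness_history = history,
                   seed = as.integer(seed))
  })
}

#' @export
predict.ga_knn_model <- function(object, newdata, tol_ppm = 600, ...) {
  idx <- align_columns(object$peak_masses, newdata, tol_ppm)
  x <- intensity_values(newdata)[, idx, drop = FALSE]
  z <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  knn_predict(object$train_z, object$train_y, z, object$k)
}

# ---- external validation ----------------------------------------------------

#' Validate a classifier on an independent labelled test set
#'
#' Predicts the pooled test set and reports one-vs-rest confusion counts and
#' accuracy / sensitivity / specificity per class.
#'
#' @param model A `maldi_classifier`.
#' @param test A labelled peak matrix.
#' @param tol_ppm Peak-alignment tolerance between model and test masses.
#' @return A tibble with one row per class: `class`, `tp`, `fn`, `tn`, `fp`,
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
external_validate <- function(model, test, tol_ppm = 600) {
  if (!nrow(test)) abort("Empty test set.")
  if (!("strain" %in% names(test))) abort("Test matrix needs a `strain` column.")
  pred <- predict(model, test, tol_ppm = tol_ppm)
  truth <- test$strain
  purrr::map(model$classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- sum(truth != cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    bind_cols(tibble(class = cl, tp = tp, fn = fn, tn = tn, fp = fp),
              metrics_from_counts(tp, fn, tn, fp))
  }) |> bind_rows()
}

# ---- broom-style methods ----------------------------------------------------

#' @export
tidy.maldi_classifier <- function(x, ...) {
  out <- tibble(peak_mass = x$peak_masses)
  if (x$kind == "qc") {
    out$p_value <- x$p_values
    out$weight <- x$weights
  }
  out
}

#' @export
glance.maldi_classifier <- function(x, ...) {
  tibble(kind = x$kind,
         n_classes = length(x$classes),
         n_peaks = length(x$peak_masses),
         cv_accuracy = if (!is.null(x$cv_accuracy)) x$cv_accuracy else NA_real_)
}
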
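# Shared fixtures, built in code.

# The seven quantified biomarker profiles (per-strain mean +/- sd).
quant_profiles <- function() reference_profiles("discriminant")

# A tiny two-strain profile set with strong separation on one peak.
toy_profiles <- function() {
  strain_profiles(data.frame(
    strain = rep(c("A", "B"), each = 2L),
    mass = rep(c(3000, 7000), 2L),
    mean = c(10, 2, 2, 10),
    sd = c(0.5, 0.2, 0.2, 0.5)
  ))
}

# A small deterministic spectrum: one Gaussian on a uniform grid.
gaussian_spectrum <- function(center = 5000, height = 10, fwhm = 5,
                              from = 4900, to = 5100, step = 0.5,
                              baseline = 0) {
  mz <- seq(from, to, by = step)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  tibble::tibble(mz = mz,
                 intensity = height * exp(-(mz - center)^2 / (2 * sigma^2)) +
                   baseline)
}

# Labelled peak matrix built directly from given class means/sds.
matrix_from_normals <- function(means, sds, n, masses, seed) {
  prof <- data.frame(
    strain = rep(rownames(means), times = ncol(means)),
    mass = rep(masses, each = nrow(means)),
    mean = as.vector(means),
    sd = as.vector(sds)
  )
  simulate_peak_matrix(strain_profiles(prof), n_replicates = n, seed = seed)
}

# Brute-force sliding min / max over a window in x-units (top-hat oracle).
brute_running <- function(x, y, half_width, fn) {
  vapply(seq_along(x), function(i) {
    fn(y[abs(x - x[i]) <= half_width])
  }, numeric(1))
}

brute_top_hat <- function(x, y, window) {
  half <- window / 2
  eroded <- brute_running(x, y, half, min)
  brute_running(x, eroded, half, max)
}

# Brute-force Kruskal-Wallis H from mid-ranks with tie correction.
brute_kruskal_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Brute-force Anderson-Darling A^2 via the explicit order-statistic sum.
brute_ad_a2 <- function(x) {
  x <- sort(x)
  n <- length(x)
  z <- pnorm((x - mean(x)) / sd(x))
  z <- pmin(pmax(z, 1e-17), 1 - 1e-17)
  total <- 0
  for (i in seq_len(n)) {
    total <- total + (2 * i - 1) * (log(z[i]) + log(1 - z[n + 1 - i]))
  }
  -n - total / n
}

# 2-D convex hull disjointness: no vertex containment and no edge crossings.
hulls_disjoint <- function(a, b) {
  ha <- a[grDevices::chull(a), , drop = FALSE]
  hb <- b[grDevices::chull(b), , drop = FALSE]
  point_in <- function(p, poly) {
    n <- nrow(poly)
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((poly[i, 2] > p[2]) != (poly[j, 2] > p[2]) &&
          p[1] < (poly[j, 1] - poly[i, 1]) * (p[2] - poly[i, 2]) /
            (poly[j, 2] - poly[i, 2]) + poly[i, 1]) {
        inside <- !inside
      }
      j <- i
    }
    inside
  }
  segs_cross <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(nrow(ha))) if (point_in(ha[i, ], hb)) return(FALSE)
  for (i in seq_len(nrow(hb))) if (point_in(hb[i, ], ha)) return(FALSE)
  na <- nrow(ha); nb <- nrow(hb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (segs_cross(ha[i, ], ha[i %% na + 1, ], hb[j, ], hb[j %% nb + 1, ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}
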
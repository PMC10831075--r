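# ggplot2 views of spectra, gel-style batches, PCA results and peak pairs.

#' Plot spectra traces
#'
#' @param batch Spectra tibble.
#' @param max_spectra Cap on traces drawn.
#' @return A ggplot object (intensity vs m/z, coloured by strain).
#' @export
plot_spectra <- function(batch, max_spectra = 9) {
  check_batch(batch)
  batch <- head(batch, max_spectra)
  long <- batch |>
    mutate(id = paste(.data$strain, .data$replicate)) |>
    tidyr::unnest("spectrum")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mz, y = .data$intensity,
                                     group = .data$id, colour = .data$strain)) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.8) +
    ggplot2::labs(x = "m/z (Da)", y = "intensity (a.u.)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Pseudo-gel view of a spectra batch
#'
#' Replicates are stacked as horizontal lanes whose colour encodes intensity,
#' faceted by strain.
#'
#' @param batch Spectra tibble (on a common grid).
#' @param trans Intensity transform for the fill scale (default `"sqrt"`).
#' @return A ggplot object.
#' @export
plot_gel_view <- function(batch, trans = "sqrt") {
  check_batch(batch)
  long <- tidyr::unnest(batch, "spectrum")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mz, y = factor(.data$replicate),
                                     fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$strain)) +
    ggplot2::scale_fill_viridis_c(trans = trans) +
    ggplot2::labs(x = "m/z (Da)", y = "replicate", fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Scatter plot of two peaks' intensities across classes
#'
#' @param m Peak matrix with `strain` labels.
#' @param mass_x,mass_y Peak masses (matched to the nearest column).
#' @param ellipse Draw 95% normal confidence ellipses per class?
#' @return A ggplot object.
#' @export
plot_peak_pair <- function(m, mass_x, mass_y, ellipse = TRUE) {
  centres <- peak_centers(m)
  jx <- which.min(abs(centres - mass_x))
  jy <- which.min(abs(centres - mass_y))
  vals <- intensity_values(m)
  df <- tibble(strain = m$strain, x = vals[, jx], y = vals[, jy])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$strain)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("%.0f Da (a.u.)", centres[jx]),
                  y = sprintf("%.0f Da (a.u.)", centres[jy]), colour = NULL) +
    ggplot2::theme_minimal()
  if (ellipse) p <- p + ggplot2::stat_ellipse(level = 0.95)
  p
}

#' @export
autoplot.maldi_pca <- function(object, loadings = FALSE, ...) {
  if (loadings) {
    df <- object$loadings
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
        ggplot2::geom_point() +
        ggplot2::geom_text(ggplot2::aes(label = round(.data$mass)),
                           vjust = -0.6, size = 3) +
        ggplot2::labs(title = "PCA loadings") +
        ggplot2::theme_minimal()
    )
  }
  df <- object$scores
  ev <- object$explained_variance_fraction
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if ("strain" %in% names(df)) {
    p <- p + ggplot2::aes(colour = .data$strain)
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("PC1 (%.0f%%)", 100 * ev[1L]),
                  y = sprintf("PC2 (%.0f%%)", 100 * ev[2L]), colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
tidy.maldi_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                           ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
         scores = x$scores,
         loadings = x$loadings,
         eigenvalues = tibble(
           component = seq_along(x$all_variance_fractions),
           explained_variance_fraction = x$all_variance_fractions,
           cumulative = cumsum(x$all_variance_fractions)))
}

#' @export
glance.maldi_pca <- function(x, ...) {
  tibble(n_components = length(x$explained_variance_fraction),
         pc1_fraction = x$explained_variance_fraction[1L],
         pc2_fraction = if (length(x$explained_variance_fraction) > 1L)
           x$explained_variance_fraction[2L] else NA_real_)
}
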
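# Main-spectrum-profile (MSP) construction and log-score identification with
# the standard confidence bands (>= 2.00 high, 1.70-1.99 low, < 1.70 none).

new_msp_record <- function(name, peaks, n_source_spectra,
                           created_from_seed = NA_integer_) {
  stopifnot(is.character(name), is.data.frame(peaks))
  peaks <- as_tibble(peaks)[order(peaks$mz), ]
  structure(list(name = name, peaks = peaks,
                 n_source_spectra = as.integer(n_source_spectra),
                 created_from_seed = created_from_seed),
            class = "msp_record")
}

#' @export
print.msp_record <- function(x, ...) {
  cat(sprintf("<MSP> %s: %d peaks from %d spectra\n",
              x$name, nrow(x$peaks), x$n_source_spectra))
  invisible(x)
}

#' Bundle MSP records into a reference library
#'
#' @param ... `msp_record` objects (or a single list of them).
#' @param version Library version label.
#' @return An `msp_library`: a named list of records. Duplicate record names
#'   are an error.
#' @export
msp_library <- function(..., version = "1") {
  recs <- list(...)
  if (length(recs) == 1L && !inherits(recs[[1L]], "msp_record") &&
      is.list(recs[[1L]])) {
    recs <- recs[[1L]]
  }
  stopifnot(all(purrr::map_lgl(recs, inherits, "msp_record")))
  nms <- purrr::map_chr(recs, "name")
  if (anyDuplicated(nms)) abort("Duplicate MSP record names.")
  structure(setNames(recs, nms), version = version, class = "msp_library")
}

#' @export
print.msp_library <- function(x, ...) {
  cat(sprintf("<MSP library v%s> %d records: %s\n", attr(x, "version"),
              length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}

# Picked peaks of one spectrum with intensities normalised so the peak
# intensities sum to 100 (makes records and queries scale-free).
spectrum_peak_profile <- function(s, snr = 5) {
  pk <- pick_peaks(s, snr_threshold = snr)
  if (!nrow(pk)) return(tibble(mz = double(), intensity = double()))
  bg <- local_background(s$intensity, s$mz)
  heights <- purrr::map_dbl(seq_len(nrow(pk)), function(j) {
    win <- which(s$mz >= pk$left[j] & s$mz <= pk$right[j])
    i <- win[which.max(s$intensity[win])]
    max(refine_apex(s$mz, s$intensity, i)$height - bg[i], 0)
  })
  keep <- heights > 0
  tibble(mz = pk$center[keep], intensity = 100 * heights[keep] / sum(heights[keep]))
}

#' Build a main spectrum profile (MSP) from replicate spectra
#'
#' Peaks are picked per replicate, pooled, and clustered by single-linkage
#' chaining: a new cluster starts wherever the gap to the previous peak
#' exceeds `tol_ppm`. Clusters seen in at least `min_frequency` of the
#' replicates become MSP peaks carrying the cluster's mean normalised
#' intensity and its observed frequency.
#'
#' @param batch Preprocessed spectra tibble (at least 3 replicates).
#' @param name Record name (defaults to the batch's strain label).
#' @param min_frequency Minimal fraction of replicates containing a peak
#'   (default 0.25).
#' @param tol_ppm Peak clustering tolerance in ppm (default 600).
#' @param snr Per-replicate peak-picking signal-to-noise threshold.
#' @param seed Seed recorded on the resulting record (provenance only).
#' @return An `msp_record`.
#' @export
build_msp <- function(batch, name = NULL, min_frequency = 0.25, tol_ppm = 600,
                      snr = 5, seed = NA_integer_) {
  check_batch(batch)
  if (nrow(batch) < 3L) abort("Building an MSP requires at least 3 replicate spectra.")
  if (is.null(name)) {
    name <- if ("strain" %in% names(batch)) as.character(batch$strain[1L]) else "MSP"
  }
  profs <- purrr::imap(batch$spectrum, function(s, i) {
    pr <- spectrum_peak_profile(s, snr = snr)
    pr$spectrum_id <- i
    pr
  }) |> bind_rows()
  if (!nrow(profs)) abort("No peaks found in any replicate.")
  profs <- arrange(profs, .data$mz)
  gap_rel <- c(Inf, diff(profs$mz) / head(profs$mz, -1L))
  profs$cluster <- cumsum(gap_rel > tol_ppm * 1e-6)
  n_spec <- nrow(batch)
  peaks <- profs |>
    group_by(.data$cluster) |>
    summarise(mz = mean(.data$mz),
              mean_intensity = mean(.data$intensity),
              frequency = dplyr::n_distinct(.data$spectrum_id) / n_spec,
              .groups = "drop") |>
    filter(.data$frequency >= min_frequency) |>
    select("mz", "mean_intensity", "frequency") |>
    arrange(.data$mz)
  new_msp_record(name, peaks, n_source_spectra = n_spec,
                 created_from_seed = seed)
}

#' Log-score similarity between a query spectrum and an MSP
#'
#' The score is `3 + log10(s1 * s2 * s3)`, clipped to `[0, 3]`, from three
#' sub-scores in `(0, 1]`:
#' * `s1`: frequency-weighted fraction of MSP peaks matched in the query
#'   (within `tol_ppm`),
#' * `s2`: intensity-weighted fraction of query peaks matched in the MSP,
#' * `s3`: intensity agreement over matched peaks,
#'   `exp(-penalty * rms(centred log intensity ratios))`, median-centred so a
#'   global intensity rescaling of the query leaves the score unchanged.
#'
#' A perfect match (all peaks shared, identical relative intensities) scores
#' 3; a query sharing no peaks with the record scores 0. Deterministic.
#'
#' @param query Preprocessed spectrum tibble, or a precomputed peak profile
#'   (`mz`, `intensity`) tibble as from picked peaks.
#' @param record An `msp_record`.
#' @param tol_ppm Symmetric peak-match tolerance (default 600 ppm).
#' @param intensity_penalty Weight of the intensity-agreement penalty
#'   (default 3).
#' @param snr Signal-to-noise threshold when `query` is a raw spectrum.
#' @return A single log-score in `[0, 3]`.
#' @export
log_score <- function(query, record, tol_ppm = 600, intensity_penalty = 3,
                      snr = 5) {
  stopifnot(inherits(record, "msp_record"))
  if (!nrow(record$peaks)) abort("Empty MSP record.")
  qp <- if (is.data.frame(query) && !("intensity" %in% names(query))) {
    abort("`query` must carry intensities.")
  } else if (nrow(query) > 50L || !all(c("mz", "intensity") %in% names(query))) {
    spectrum_peak_profile(query, snr = snr)
  } else {
    q <- as_tibble(query)[c("mz", "intensity")]
    q$intensity <- 100 * q$intensity / sum(q$intensity)
    q
  }
  if (!nrow(qp)) return(0)
  rp <- record$peaks
  # one-to-one nearest matching within tolerance, greedy by proximity
  match_rq <- purrr::map_int(seq_len(nrow(rp)), function(i) {
    d <- abs(qp$mz - rp$mz[i]) / rp$mz[i] * 1e6
    j <- which.min(d)
    if (d[j] <= tol_ppm) j else NA_integer_
  })
  matched_r <- which(!is.na(match_rq))
  s1 <- sum(rp$frequency[matched_r]) / sum(rp$frequency)
  matched_q <- unique(match_rq[matched_r])
  s2 <- sum(qp$intensity[matched_q]) / sum(qp$intensity)
  if (!length(matched_r) || s1 <= 0 || s2 <= 0) return(0)
  dl <- log(qp$intensity[match_rq[matched_r]]) - log(rp$mean_intensity[matched_r])
  dl <- dl - median(dl)
  s3 <- exp(-intensity_penalty * sqrt(mean(dl^2)))
  g <- s1 * s2 * s3
  if (g <= 0) return(0)
  min(max(3 + log10(g), 0), 3)
}

#' Identification confidence band of a log-score
#'
#' @param score Numeric log-score(s).
#' @return `"high_confidence"` for scores in `[2.00, 3.00]`,
#'   `"low_confidence"` for `[1.70, 2.00)`, else `"no_identification"`.
#' @export
identification_category <- function(score) {
  dplyr::case_when(
    score >= 2.0 ~ "high_confidence",
    score >= 1.7 ~ "low_confidence",
    .default = "no_identification"
  )
}

#' Identify an unknown spectrum against an MSP library
#'
#' Scores the query against every record and ranks the matches; the reported
#' confidence category is that of the top log-score. The ranking is
#' invariant to the record order in the library (ties broken by name).
#'
#' @param query Preprocessed spectrum tibble.
#' @param library An `msp_library`.
#' @inheritParams log_score
#' @return A tibble of class `maldi_identification`, ranked by descending
#'   `log_score`, with columns `rank`, `record`, `log_score`, `category`;
#'   the top category is also attached as attribute `"category"`.
#' @export
identify_spectrum <- function(query, library, tol_ppm = 600,
                              intensity_penalty = 3, snr = 5) {
  stopifnot(inherits(library, "msp_library"))
  if (!length(library)) abort("Empty MSP library.")
  qp <- if (is.data.frame(query) && all(c("mz", "intensity") %in% names(query)) &&
            nrow(query) <= 50L) {
    q <- as_tibble(query)[c("mz", "intensity")]
    q$intensity <- 100 * q$intensity / sum(q$intensity)
    q
  } else {
    spectrum_peak_profile(query, snr = snr)
  }
  scores <- purrr::map_dbl(library, function(rec) {
    log_score(qp, rec, tol_ppm = tol_ppm, intensity_penalty = intensity_penalty)
  })
  out <- tibble(record = names(library), log_score = unname(scores)) |>
    arrange(dplyr::desc(.data$log_score), .data$record) |>
    mutate(rank = row_number(),
           category = identification_category(.data$log_score)) |>
    select("rank", "record", "log_score", "category")
  attr(out, "category") <- out$category[1L]
  class(out) <- c("maldi_identification", class(out))
  out
}

#' @export
tidy.msp_record <- function(x, ...) {
  mutate(x$peaks, record = x$name, .before = 1L)
}

#' @export
glance.msp_record <- function(x, ...) {
  tibble(record = x$name, n_peaks = nrow(x$peaks),
         n_source_spectra = x$n_source_spectra,
         created_from_seed = x$created_from_seed)
}
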
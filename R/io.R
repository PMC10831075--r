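# Readers and writers: two-column text spectra, mzML (via mzR), MSP library
# JSON, and CSV peak matrices.

#' Read a single mass spectrum
#'
#' Supports a plain two-column text dialect (whitespace- or comma-separated
#' `m/z intensity` rows, `#` comments, optional header line) and mzML. The
#' m/z axis is sorted and exact duplicates are averaged; a non-monotone axis
#' after that, an empty file, NaN values or negative m/z are format errors.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"xy"` or `"mzml"`.
#' @return A spectrum tibble `(mz, intensity)`.
#' @export
read_spectrum <- function(path, format = c("auto", "xy", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", tolower(path))) "mzml" else "xy"
  }
  if (format == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      abort("Reading mzML requires the mzR package.")
    }
    handle <- mzR::openMSfile(path)
    on.exit(mzR::close(handle), add = TRUE)
    pk <- mzR::peaks(handle, 1L)
    df <- tibble(mz = pk[, 1L], intensity = pk[, 2L])
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) abort(sprintf("Empty spectrum file: %s", path))
    sep_comma <- grepl(",", lines[[length(lines)]], fixed = TRUE)
    parts <- strsplit(lines, if (sep_comma) "[,[:space:]]+" else "[[:space:]]+")
    # tolerate one fully non-numeric header line
    num <- suppressWarnings(lapply(parts, as.numeric))
    if (all(is.na(num[[1L]])) && length(num) > 1L) num <- num[-1L]
    if (any(lengths(num) < 2L)) abort(sprintf("Malformed spectrum file: %s", path))
    df <- tibble(mz = purrr::map_dbl(num, 1L), intensity = purrr::map_dbl(num, 2L))
  }
  if (anyNA(df$mz) || anyNA(df$intensity)) {
    abort(sprintf("NaN values in spectrum file: %s", path))
  }
  if (any(df$mz <= 0)) abort(sprintf("Non-positive m/z in spectrum file: %s", path))
  df <- df |>
    group_by(.data$mz) |>
    summarise(intensity = mean(.data$intensity), .groups = "drop") |>
    arrange(.data$mz)
  check_spectrum(df, arg = path)
  df
}

#' Write a single mass spectrum
#'
#' @param s Spectrum tibble `(mz, intensity)`.
#' @param path Output file.
#' @param format `"auto"` (by extension), `"xy"` or `"mzml"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("auto", "xy", "mzml")) {
  format <- match.arg(format)
  check_spectrum(s)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", tolower(path))) "mzml" else "xy"
  }
  if (format == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      abort("Writing mzML requires the mzR package.")
    }
    hdr <- mzml_header(s)
    mzR::writeMSData(list(cbind(s$mz, s$intensity)), file = path, header = hdr)
  } else {
    writeLines(c("# m/z intensity", sprintf("%.6f %.8g", s$mz, s$intensity)), path)
  }
  invisible(path)
}

mzml_header <- function(s) {
  data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = nrow(s), totIonCurrent = sum(s$intensity), retentionTime = 0,
    basePeakMZ = s$mz[which.max(s$intensity)], basePeakIntensity = max(s$intensity),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = min(s$mz), highMZ = max(s$mz),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = "", spectrumId = "scan=1",
    centroided = FALSE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = min(s$mz), scanWindowUpperLimit = max(s$mz),
    stringsAsFactors = FALSE
  )
}

#' Write a batch of spectra with a manifest
#'
#' One file per spectrum plus `manifest.csv` (filename, strain, replicate,
#' seed) in `dir`.
#'
#' @param batch Spectra tibble (`strain`, `replicate`, `spectrum`).
#' @param dir Output directory (created if needed).
#' @param format `"xy"` or `"mzml"`.
#' @param seed Seed recorded in the manifest (informational).
#' @return The manifest tibble, invisibly.
#' @export
write_spectra <- function(batch, dir, format = c("xy", "mzml"), seed = NA_integer_) {
  format <- match.arg(format)
  check_batch(batch)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "mzml") "mzML" else "txt"
  manifest <- batch |>
    mutate(filename = sprintf("%s_rep%02d.%s",
                              gsub("[^A-Za-z0-9]+", "_", .data$strain),
                              .data$replicate, ext),
           seed = seed) |>
    select("filename", "strain", "replicate", "seed")
  purrr::walk2(batch$spectrum, manifest$filename, function(s, f) {
    write_spectrum(s, file.path(dir, f), format = format)
  })
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a batch of spectra written by [write_spectra()]
#'
#' @param dir Directory containing `manifest.csv`.
#' @return A spectra tibble (`strain`, `replicate`, `spectrum`).
#' @export
read_spectra <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) abort(sprintf("No manifest.csv under %s", dir))
  manifest <- readr::read_csv(mf, show_col_types = FALSE)
  manifest |>
    mutate(spectrum = purrr::map(.data$filename,
                                 ~ read_spectrum(file.path(dir, .x)))) |>
    select("strain", "replicate", "spectrum")
}

#' Write / read an MSP reference library as JSON
#'
#' The serialisation is a documented JSON schema: a `version` string and one
#' record per strain with `name`, `n_source_spectra`, `created_from_seed` and
#' parallel `peaks` arrays (`mz`, `mean_intensity`, `frequency`). Round trips
#' are lossless at double precision. Duplicate record names are an error.
#'
#' @param library An `msp_library` object (see [msp_library()]).
#' @param path JSON file path.
#' @return `write_msp_library()` returns `path` invisibly;
#'   `read_msp_library()` returns an `msp_library`.
#' @export
write_msp_library <- function(library, path) {
  stopifnot(inherits(library, "msp_library"))
  payload <- list(
    version = attr(library, "version"),
    records = purrr::map(library, function(rec) {
      list(name = rec$name,
           n_source_spectra = rec$n_source_spectra,
           created_from_seed = rec$created_from_seed,
           peaks = list(mz = rec$peaks$mz,
                        mean_intensity = rec$peaks$mean_intensity,
                        frequency = rec$peaks$frequency))
    })
  )
  # I(17) significant digits: lossless double -> decimal -> double round trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_msp_library
#' @export
read_msp_library <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  recs <- purrr::map(payload$records, function(r) {
    new_msp_record(
      name = r$name,
      peaks = tibble(mz = as.numeric(unlist(r$peaks$mz)),
                     mean_intensity = as.numeric(unlist(r$peaks$mean_intensity)),
                     frequency = as.numeric(unlist(r$peaks$frequency))),
      n_source_spectra = as.integer(r$n_source_spectra),
      created_from_seed = if (is.null(r$created_from_seed)) NA_integer_ else
        as.integer(r$created_from_seed)
    )
  })
  do.call(msp_library, c(recs, list(version = payload$version %||% "1")))
}

#' Write / read a labelled peak-intensity matrix as CSV
#'
#' Column headers carry the peak masses in Da; `strain` and `replicate` label
#' the rows.
#'
#' @param m A peak-matrix tibble (see [peak_matrix()]).
#' @param path CSV file path.
#' @return `write_peak_matrix()` returns `path` invisibly;
#'   `read_peak_matrix()` the matrix tibble.
#' @export
write_peak_matrix <- function(m, path) {
  readr::write_csv(as_tibble(m), path)
  invisible(path)
}

#' @rdname write_peak_matrix
#' @export
read_peak_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  centres <- as.numeric(sub("^mz_", "", setdiff(names(df), c("strain", "replicate"))))
  new_peak_matrix(df, centres)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
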
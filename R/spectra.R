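#' Construct a raw MALDI-TOF spectrum
#'
#' A `raw_spectrum` is a continuous m/z--intensity trace together with
#' acquisition metadata: the isolate it came from, the biological replicate
#' (target spot) and the acquisition index (spectra are typically acquired in
#' several separate reads per target spot).
#'
#' @param mz Numeric vector of m/z values in Da. Need not be sorted; the
#'   constructor sorts and carries intensities along. Exact duplicates are
#'   collapsed by summing their intensities.
#' @param intensity Numeric vector of non-negative intensities (arbitrary
#'   units), same length as `mz`.
#' @param isolate_id,replicate_id Character labels for provenance.
#' @param acquisition_index Small integer, the read number within a spot.
#' @return An object of class `raw_spectrum`: a list with elements `mz`,
#'   `intensity`, `isolate_id`, `replicate_id`, `acquisition_index`.
#' @export
raw_spectrum <- function(mz, intensity, isolate_id = NA_character_,
                         replicate_id = NA_character_, acquisition_index = 1L) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (!is.numeric(mz) || !is.numeric(intensity))
    stop("mz and intensity must be numeric")
  if (anyNA(mz) || anyNA(intensity))
    stop("mz and intensity must not contain NA")
  if (any(intensity < 0))
    stop("intensities must be non-negative")
  o <- order(mz)
  mz <- as.numeric(mz[o]); intensity <- as.numeric(intensity[o])
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(list(mz = mz, intensity = intensity,
                 isolate_id = as.character(isolate_id),
                 replicate_id = as.character(replicate_id),
                 acquisition_index = as.integer(acquisition_index)),
            class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("raw_spectrum: %d points, m/z %.1f-%.1f, isolate=%s rep=%s acq=%d\n",
              length(x$mz), min(x$mz), max(x$mz),
              x$isolate_id, x$replicate_id, x$acquisition_index))
  invisible(x)
}

#' Construct a peak list
#'
#' Discrete (m/z, intensity) peaks derived from one spectrum. Intensities are
#' normalized so the maximum peak is 1.0; downstream scoring is therefore
#' invariant to the absolute intensity scale of the instrument.
#'
#' @param mz Numeric vector of peak m/z values (Da), strictly increasing after
#'   sorting.
#' @param intensity Positive peak intensities; rescaled to max 1.
#' @param source Optional list of metadata describing the originating spectrum.
#' @return An object of class `peak_list` with elements `mz`, `intensity`,
#'   `source`.
#' @export
peak_list <- function(mz, intensity, source = NULL) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  o <- order(mz)
  mz <- as.numeric(mz[o]); intensity <- as.numeric(intensity[o])
  if (length(mz) && any(duplicated(mz)))
    stop("peak m/z values must be unique")
  if (length(intensity) && any(intensity <= 0))
    stop("peak intensities must be positive")
  if (length(intensity)) intensity <- intensity / max(intensity)
  structure(list(mz = mz, intensity = intensity, source = source),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("peak_list: %d peaks", length(x$mz)))
  if (length(x$mz)) cat(sprintf(", m/z %.1f-%.1f", min(x$mz), max(x$mz)))
  cat("\n")
  invisible(x)
}

#' @export
length.peak_list <- function(x) length(x$mz)

#' Read a spectrum from disk
#'
#' Supports two-column delimited text (m/z, intensity; comma or tab separated,
#' header optional) and uncompressed mzML. Input rows in arbitrary m/z order
#' are sorted on read, so a shuffled file yields the same spectrum as a sorted
#' one.
#'
#' @param path File path.
#' @param format `"csv"` (also covers TSV) or `"mzml"`.
#' @param ... Metadata passed to [raw_spectrum()] (`isolate_id`, etc.).
#' @return A [raw_spectrum()].
#' @export
read_spectrum <- function(path, format = c("csv", "mzml"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read spectrum file: ", path)
  if (format == "csv") read_spectrum_csv(path, ...) else read_spectrum_mzml(path, ...)
}

read_spectrum_csv <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty spectrum file: ", path)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  first_data <- 1L
  probe <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  if (any(is.na(suppressWarnings(as.numeric(probe[1:2]))))) first_data <- 2L
  n <- length(lines) - first_data + 1L
  if (n < 1L) stop("no data rows in ", path)
  mz <- numeric(n); int <- numeric(n)
  for (i in seq_len(n)) {
    row <- first_data + i - 1L
    f <- strsplit(lines[[row]], sep, fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (length(f) < 2L || anyNA(v))
      stop(sprintf("non-numeric spectrum row %d in %s", row, path))
    if (v[2] < 0)
      stop(sprintf("negative intensity in spectrum row %d in %s", row, path))
    mz[i] <- v[1]; int[i] <- v[2]
  }
  raw_spectrum(mz, int, ...)
}

#' Write a spectrum as a two-column CSV
#' @param s A [raw_spectrum()].
#' @param path Destination file.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "raw_spectrum"))
  utils::write.table(data.frame(mz = s$mz, intensity = s$intensity),
                     path, sep = ",", row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

# -- minimal mzML support: one spectrum per file, 64-bit little-endian, no
#    compression. Covers the subset of the schema the pipeline writes.

b64_doubles_enc <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8, endian = "little"))
b64_doubles_dec <- function(txt, size = 8) {
  bytes <- jsonlite::base64_dec(gsub("\\s", "", txt))
  readBin(bytes, what = "numeric", n = length(bytes) %/% size, size = size,
          endian = "little")
}

#' Write a spectrum to mzML
#'
#' Emits a minimal, standard-conformant mzML document: one spectrum, 64-bit
#' little-endian uncompressed binary arrays with the usual m/z and intensity
#' controlled-vocabulary terms.
#'
#' @param s A [raw_spectrum()].
#' @param path Destination file.
#' @export
write_spectrum_mzml <- function(s, path) {
  stopifnot(inherits(s, "raw_spectrum"))
  cv <- function(acc, name, extra = "")
    sprintf('<cvParam cvRef="MS" accession="%s" name="%s"%s/>', acc, name, extra)
  arr <- function(values, acc, name) {
    enc <- b64_doubles_enc(values)
    paste0('<binaryDataArray encodedLength="', nchar(enc), '">',
           cv("MS:1000523", "64-bit float"),
           cv("MS:1000576", "no compression"),
           cv(acc, name),
           "<binary>", enc, "</binary></binaryDataArray>")
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<run id="', xml_escape(paste0(s$isolate_id, "_", s$replicate_id)), '">',
    '<spectrumList count="1">',
    '<spectrum index="0" id="scan=1" defaultArrayLength="', length(s$mz), '">',
    '<binaryDataArrayList count="2">',
    arr(s$mz, "MS:1000514", "m/z array"),
    arr(s$intensity, "MS:1000515", "intensity array"),
    '</binaryDataArrayList></spectrum></spectrumList></run></mzML>')
  writeLines(doc, path)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

read_spectrum_mzml <- function(path, ...) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  arrays <- xml2::xml_find_all(doc, ".//binaryDataArray")
  if (!length(arrays)) stop("no binary data arrays in mzML file: ", path)
  mz <- NULL; int <- NULL
  for (a in arrays) {
    accs <- xml2::xml_attr(xml2::xml_find_all(a, ".//cvParam"), "accession")
    if ("MS:1000574" %in% accs)
      stop("compressed mzML binary arrays are not supported: ", path)
    size <- if ("MS:1000521" %in% accs) 4L else 8L
    values <- b64_doubles_dec(xml2::xml_text(xml2::xml_find_first(a, ".//binary")),
                              size = size)
    if ("MS:1000514" %in% accs) mz <- values
    if ("MS:1000515" %in% accs) int <- values
  }
  if (is.null(mz) || is.null(int))
    stop("mzML file lacks m/z or intensity array: ", path)
  raw_spectrum(mz, int, ...)
}

#' SNIP-style iterative baseline subtraction
#'
#' Estimates the baseline by iterative clipping: each pass replaces every
#' point by the minimum of itself and the mean of its neighbours at distance
#' `half_window`, so features narrower than the window are clipped away while
#' smooth baselines (constant, linear ramps) are preserved exactly and then
#' removed in full. Near the spectrum ends the window shrinks symmetrically
#' (to `min(half_window, i-1, n-i)` points), which keeps the neighbour mean
#' unbiased on sloping baselines at the boundaries. The m/z axis is never
#' altered.
#'
#' @param s A [raw_spectrum()].
#' @param half_window Clipping half-window in points (default 100; with a
#'   1 Da grid this is 100 Da, several times the width of a protein peak).
#' @param iterations Number of clipping passes (default 30).
#' @return A [raw_spectrum()] with the estimated baseline removed; intensities
#'   are clamped at zero.
#' @export
subtract_baseline <- function(s, half_window = 100L, iterations = 30L) {
  stopifnot(inherits(s, "raw_spectrum"))
  half_window <- as.integer(half_window); iterations <- as.integer(iterations)
  if (half_window < 1L || iterations < 1L)
    stop("half_window and iterations must be >= 1")
  n <- length(s$mz)
  if (n < 2L * half_window + 1L)
    stop("spectrum too short for baseline half_window ", half_window)
  b <- s$intensity
  idx <- seq_len(n)
  w <- pmin(half_window, idx - 1L, n - idx)
  left <- idx - w
  right <- idx + w
  for (i in seq_len(iterations)) {
    clipped <- pmin(b, (b[left] + b[right]) / 2)
    if (identical(clipped, b)) break
    b <- clipped
  }
  out <- s
  out$intensity <- pmax(s$intensity - b, 0)
  out
}

#' Savitzky-Golay smoothing
#'
#' Polynomial moving-window smoothing of the intensity trace; the m/z axis and
#' trace length are unchanged. Polynomials up to `polyorder` are reproduced
#' exactly, so constant and straight-line spectra pass through unaltered.
#'
#' @param s A [raw_spectrum()].
#' @param window Odd window length in points (default 21).
#' @param polyorder Polynomial order (default 3), must be < `window`.
#' @return A smoothed [raw_spectrum()]; intensities clamped at zero.
#' @export
smooth_spectrum <- function(s, window = 21L, polyorder = 3L) {
  stopifnot(inherits(s, "raw_spectrum"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  if (length(s$mz) < window) stop("spectrum shorter than smoothing window")
  out <- s
  out$intensity <- pmax(signal::sgolayfilt(s$intensity, p = polyorder, n = window), 0)
  out
}

# Noise scale of a trace: MAD (scaled to Gaussian sigma) of the residual
# around a running median wider than any peak-smoothing window. The running
# median detrends peaks and residual baseline; MAD is robust to the small
# fraction of points occupied by true peaks.
noise_sd_estimate <- function(intensity, k = 99L) {
  n <- length(intensity)
  if (n < 3L) return(0)
  k <- min(k, if (n %% 2L) n else n - 1L)
  stats::mad(intensity - stats::runmed(intensity, k))
}

#' Detect peaks in a preprocessed spectrum
#'
#' Local maxima are measured by their height above a wide running median
#' (which tracks residual offset left by smoothing and clipping) and kept
#' when that height exceeds `snr` times a robust noise estimate
#' (median-absolute-deviation based, scaled to Gaussian sigma) and
#' `rel_floor` times the base (largest) peak height, restricted to
#' `[min_mz, max_mz]`. Output intensities are re-normalized to a maximum of
#' 1; together with the relative floor this makes detection and all
#' downstream scoring invariant to a global intensity rescaling.
#'
#' @param s A preprocessed (baseline-subtracted, smoothed) [raw_spectrum()].
#' @param snr Signal-to-noise threshold (default 3).
#' @param min_mz,max_mz Analyzed mass range in Da (defaults 2000 and 20000).
#' @param rel_floor Minimum peak height relative to the base peak
#'   (default 0.01).
#' @return A [peak_list()]; may be empty.
#' @export
detect_peaks <- function(s, snr = 3, min_mz = 2000, max_mz = 20000,
                         rel_floor = 0.01) {
  stopifnot(inherits(s, "raw_spectrum"))
  if (snr <= 0) stop("snr must be positive")
  if (min_mz >= max_mz) stop("min_mz must be below max_mz")
  y <- s$intensity
  n <- length(y)
  empty <- peak_list(numeric(0), numeric(0),
                     source = list(isolate_id = s$isolate_id,
                                   replicate_id = s$replicate_id,
                                   acquisition_index = s$acquisition_index))
  if (n < 3L) return(empty)
  k <- min(99L, if (n %% 2L) n else n - 1L)
  height <- y - stats::runmed(y, k)
  d <- diff(y)
  # strict rise before, non-rise after; plateau maxima take the first point
  is_max <- c(FALSE, d[-length(d)] > 0 & d[-1] <= 0, FALSE)
  thr <- snr * noise_sd_estimate(y, k)
  cand <- is_max & height > thr & height > 0 & s$mz >= min_mz & s$mz <= max_mz
  if (!any(cand)) return(empty)
  cand <- cand & height >= rel_floor * max(height[cand])
  if (!any(cand)) return(empty)
  peak_list(s$mz[cand], height[cand],
            source = list(isolate_id = s$isolate_id,
                          replicate_id = s$replicate_id,
                          acquisition_index = s$acquisition_index))
}

#' Quality-control a spectrum within a replicate cohort
#'
#' Implements the two elimination rules applied when curating replicate
#' acquisitions: a flat-line check (too little dynamic range, or too few
#' detectable peaks) and an outlier check (the spectrum's mean correlation to
#' the other cohort members, computed on 1-Da binned profiles, falls below a
#' cutoff). Both flags are assigned independently; the result does not depend
#' on the order of the cohort.
#'
#' @param s A preprocessed [raw_spectrum()].
#' @param cohort List of [raw_spectrum()] replicates (may include `s` itself;
#'   it is excluded from its own comparison set).
#' @param min_peaks Minimum detectable peaks before a spectrum counts as flat
#'   (default 10).
#' @param dynamic_floor Minimum (max-min)/max intensity ratio (default 0.01).
#' @param cor_cutoff Minimum mean cohort correlation (default 0.5).
#' @param snr Signal-to-noise threshold used for the peak-count check.
#' @return A list of class `qc_report`: `flat_line`, `outlier`, `reason`.
#' @export
qc_spectrum <- function(s, cohort, min_peaks = 10L, dynamic_floor = 0.01,
                        cor_cutoff = 0.5, snr = 3) {
  stopifnot(inherits(s, "raw_spectrum"))
  if (!length(cohort)) stop("cohort must contain at least one spectrum")
  reasons <- character(0)
  mx <- if (length(s$intensity)) max(s$intensity) else 0
  dyn <- if (mx > 0) (mx - min(s$intensity)) / mx else 0
  flat <- FALSE
  if (dyn < dynamic_floor) {
    flat <- TRUE
    reasons <- c(reasons, sprintf("dynamic range %.4f below floor %.4f", dyn, dynamic_floor))
  }
  npk <- length(detect_peaks(s, snr = snr, min_mz = min(s$mz), max_mz = max(s$mz)))
  if (npk < min_peaks) {
    flat <- TRUE
    reasons <- c(reasons, sprintf("only %d detectable peaks (minimum %d)", npk, min_peaks))
  }
  others <- Filter(function(o) !same_acquisition(o, s), cohort)
  outlier <- FALSE
  if (length(others)) {
    grid <- profile_grid(c(list(s), others))
    ps <- binned_trace(s, grid)
    cors <- vapply(others, function(o) {
      po <- binned_trace(o, grid)
      if (stats::sd(ps) == 0 || stats::sd(po) == 0) return(0)
      stats::cor(ps, po)
    }, numeric(1))
    if (mean(cors) < cor_cutoff) {
      outlier <- TRUE
      reasons <- c(reasons, sprintf("mean cohort correlation %.3f below cutoff %.2f",
                                    mean(cors), cor_cutoff))
    }
  }
  structure(list(flat_line = flat, outlier = outlier,
                 reason = if (length(reasons)) paste(reasons, collapse = "; ") else ""),
            class = "qc_report")
}

same_acquisition <- function(a, b) {
  identical(a$isolate_id, b$isolate_id) &&
    identical(a$replicate_id, b$replicate_id) &&
    identical(a$acquisition_index, b$acquisition_index) &&
    length(a$mz) == length(b$mz) && isTRUE(all.equal(a$intensity, b$intensity))
}

profile_grid <- function(spectra, bin_width = 1) {
  lo <- floor(min(vapply(spectra, function(s) min(s$mz), numeric(1))))
  hi <- ceiling(max(vapply(spectra, function(s) max(s$mz), numeric(1))))
  seq(lo, hi + bin_width, by = bin_width)
}

binned_trace <- function(s, edges) {
  idx <- findInterval(s$mz, edges, rightmost.closed = FALSE)
  idx[idx < 1L] <- NA; idx[idx >= length(edges)] <- NA
  out <- numeric(length(edges) - 1L)
  ok <- !is.na(idx)
  if (any(ok)) {
    agg <- tapply(s$intensity[ok], idx[ok], sum)
    out[as.integer(names(agg))] <- agg
  }
  out
}

#' Full single-spectrum preprocessing
#'
#' Convenience wrapper chaining baseline subtraction, smoothing and peak
#' detection with the package defaults.
#'
#' @inheritParams subtract_baseline
#' @inheritParams detect_peaks
#' @param window,polyorder Smoothing parameters, see [smooth_spectrum()].
#' @return A [peak_list()].
#' @export
preprocess_spectrum <- function(s, half_window = 100L, iterations = 30L,
                                window = 21L, polyorder = 3L,
                                snr = 3, min_mz = 2000, max_mz = 20000) {
  s <- subtract_baseline(s, half_window, iterations)
  s <- smooth_spectrum(s, window, polyorder)
  detect_peaks(s, snr = snr, min_mz = min_mz, max_mz = max_mz)
}
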
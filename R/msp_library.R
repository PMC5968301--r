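#' Build a main spectral profile (MSP) from replicate peak lists
#'
#' An MSP is the consensus reference entry of the spectral database. Peaks are
#' clustered across replicates by greedy single-linkage chaining within an m/z
#' tolerance; each cluster's frequency is the fraction of replicates that
#' contributed a peak to it, and only clusters with frequency strictly greater
#' than `freq_floor` are retained (so a peak seen in exactly 75% of replicates
#' is excluded at the default floor). The construction is invariant to the
#' order of the replicate lists, and raising the floor can only remove peaks.
#'
#' @param replicates List of [peak_list()] objects, at least `min_spectra` of
#'   them (default 10).
#' @param entry_name Database entry name, e.g. `"Bacillus safensis_FO36b^T"`.
#' @param mz_tolerance Peak-matching tolerance in Da (default 2).
#' @param freq_floor Frequency floor in \[0,1) (default 0.75, strict).
#' @param min_spectra Minimum number of contributing peak lists (default 10).
#' @param taxon Optional list with `genus`, `species`, `strain` labels.
#' @param is_type_strain Whether the entry derives from a characterized type
#'   strain.
#' @return Object of class `msp`: `entry_name`, `taxon`, `is_type_strain`,
#'   `peaks` (data.frame `mz`, `intensity` normalized to max 1, `frequency`),
#'   `n_spectra`, `provenance`.
#' @export
build_msp <- function(replicates, entry_name, mz_tolerance = 2,
                      freq_floor = 0.75, min_spectra = 10L,
                      taxon = NULL, is_type_strain = FALSE) {
  if (length(replicates) < min_spectra)
    stop(sprintf("MSP construction requires at least %d replicate peak lists, got %d",
                 min_spectra, length(replicates)))
  stopifnot(all(vapply(replicates, inherits, logical(1), "peak_list")))
  n <- length(replicates)
  mz <- unlist(lapply(replicates, `[[`, "mz"))
  int <- unlist(lapply(replicates, `[[`, "intensity"))
  rep_id <- rep.int(seq_len(n), vapply(replicates, length, integer(1)))
  if (!length(mz))
    stop("replicate peak lists contain no peaks")
  o <- order(mz)
  mz <- mz[o]; int <- int[o]; rep_id <- rep_id[o]
  # single-linkage chaining: a gap > tolerance starts a new cluster
  cluster <- cumsum(c(1, diff(mz) > mz_tolerance))
  cl_mz <- vapply(split(seq_along(mz), cluster), function(i) {
    stats::weighted.mean(mz[i], int[i])
  }, numeric(1))
  cl_int <- vapply(split(int, cluster), mean, numeric(1))
  cl_freq <- vapply(split(rep_id, cluster), function(r) length(unique(r)) / n,
                    numeric(1))
  keep <- cl_freq > freq_floor
  if (!any(keep))
    stop("no peak cluster exceeds the frequency floor; MSP would be empty")
  pk <- data.frame(mz = cl_mz[keep], intensity = cl_int[keep],
                   frequency = cl_freq[keep])
  pk <- pk[order(pk$mz), , drop = FALSE]
  rownames(pk) <- NULL
  pk$intensity <- pk$intensity / max(pk$intensity)
  src <- lapply(replicates, function(p) p$source)
  structure(list(entry_name = as.character(entry_name),
                 taxon = taxon,
                 is_type_strain = isTRUE(is_type_strain),
                 peaks = pk,
                 n_spectra = n,
                 provenance = list(mz_tolerance = mz_tolerance,
                                   freq_floor = freq_floor,
                                   min_spectra = as.integer(min_spectra),
                                   frequency_denominator = "per contributing peak list",
                                   sources = src)),
            class = "msp")
}

#' @export
print.msp <- function(x, ...) {
  cat(sprintf("msp '%s': %d peaks from %d spectra%s\n", x$entry_name,
              nrow(x$peaks), x$n_spectra,
              if (x$is_type_strain) " (type strain)" else ""))
  invisible(x)
}

#' Convert an MSP to a peak list
#'
#' The MSP's consensus peaks as a [peak_list()], e.g. for self-scoring or
#' profile binning.
#' @param msp An [build_msp()] object.
#' @export
msp_as_peaklist <- function(msp) {
  stopifnot(inherits(msp, "msp"))
  peak_list(msp$peaks$mz, msp$peaks$intensity,
            source = list(entry_name = msp$entry_name))
}

#' Validate an MSP against its contributing replicates
#'
#' Each contributing peak list is scored against the finished MSP on the 0-3
#' log-score scale; the entry passes only if every replicate scores strictly
#' above `threshold` (default 2.7), the stringency applied when curating the
#' custom database.
#'
#' @param msp An `msp`.
#' @param replicates The contributing [peak_list()]s.
#' @param threshold Self-score threshold (default 2.7).
#' @param mz_tolerance Peak-matching tolerance in Da for scoring.
#' @return List of class `msp_validation`: `per_spectrum_scores` (data.frame
#'   `spectrum`, `log_score`), `all_pass`, `threshold`.
#' @export
validate_msp <- function(msp, replicates, threshold = 2.7, mz_tolerance = 2) {
  stopifnot(inherits(msp, "msp"))
  if (!length(replicates)) stop("no replicate peak lists supplied")
  scores <- vapply(replicates, function(p)
    score_spectrum(p, msp, mz_tolerance = mz_tolerance)$log_score, numeric(1))
  ids <- vapply(seq_along(replicates), function(i) {
    src <- replicates[[i]]$source
    if (is.list(src) && !is.null(src$replicate_id))
      paste0(src$replicate_id, ".", src$acquisition_index %||% i)
    else paste0("spectrum_", i)
  }, character(1))
  structure(list(per_spectrum_scores = data.frame(spectrum = ids, log_score = scores),
                 all_pass = all(scores > threshold),
                 threshold = threshold),
            class = "msp_validation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a spectral library
#'
#' @param entries List of `msp` objects with unique entry names.
#' @return Object of class `spectral_library`: `entries` (named list),
#'   `schema_version`, `created`.
#' @export
spectral_library <- function(entries) {
  stopifnot(all(vapply(entries, inherits, logical(1), "msp")))
  nm <- vapply(entries, `[[`, character(1), "entry_name")
  if (anyDuplicated(nm))
    stop("duplicate entry names in library: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(entries) <- nm
  structure(list(entries = entries, schema_version = "1.0",
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("spectral_library: %d entries (schema %s)\n",
              length(x$entries), x$schema_version))
  invisible(x)
}

#' @export
length.spectral_library <- function(x) length(x$entries)

#' Save a spectral library as versioned JSON
#'
#' The library is serialized to a documented JSON schema; text and integer
#' fields round-trip exactly and numeric peak data to full double precision.
#'
#' @param lib A [spectral_library()].
#' @param path Destination file.
#' @export
save_library <- function(lib, path) {
  stopifnot(inherits(lib, "spectral_library"))
  entries <- lapply(unname(lib$entries), function(e) {
    list(entry_name = e$entry_name,
         taxon = e$taxon,
         is_type_strain = e$is_type_strain,
         peaks = list(mz = e$peaks$mz, intensity = e$peaks$intensity,
                      frequency = e$peaks$frequency),
         n_spectra = e$n_spectra,
         provenance = e$provenance[c("mz_tolerance", "freq_floor", "min_spectra",
                                     "frequency_denominator")])
  })
  jsonlite::write_json(list(schema_version = lib$schema_version,
                            created = lib$created,
                            entries = entries),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a spectral library from JSON
#'
#' @param path JSON file written by [save_library()].
#' @return A [spectral_library()].
#' @export
load_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse library JSON: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(obj$schema_version))
    stop("library file lacks a schema_version field")
  if (!identical(obj$schema_version, "1.0"))
    stop("unsupported library schema version: ", obj$schema_version)
  entries <- lapply(obj$entries, function(e) {
    pk <- data.frame(mz = unlist(e$peaks$mz),
                     intensity = unlist(e$peaks$intensity),
                     frequency = unlist(e$peaks$frequency))
    structure(list(entry_name = e$entry_name,
                   taxon = e$taxon,
                   is_type_strain = isTRUE(e$is_type_strain),
                   peaks = pk,
                   n_spectra = as.integer(e$n_spectra),
                   provenance = e$provenance),
              class = "msp")
  })
  nm <- vapply(entries, `[[`, character(1), "entry_name")
  if (anyDuplicated(nm))
    stop("integrity error: duplicate entry names in library file: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  lib <- spectral_library(entries)
  lib$created <- obj$created %||% lib$created
  lib
}
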
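#' Score a peak list against an MSP on the 0-3 log-score scale
#'
#' The score is a three-component composite, the form widely used to describe
#' whole-cell MALDI-TOF biotyping scores: the fraction of query peaks matched
#' to the reference (`s_query`), the fraction of reference peaks matched
#' (`s_ref`, by default weighted by each reference peak's replicate
#' frequency, so missing an always-present peak costs more than missing a
#' rarely-seen one) and an intensity-pattern agreement term (`s_int`, the
#' non-negative Pearson correlation of matched-pair intensities). The final
#' score is
#' \deqn{\max(0,\ \log_{10}(1000\, s_q\, s_r\, s_i))}
#' so identity scores 3.0 and unrelated peak sets score 0. Peaks are matched
#' greedily by nearest m/z within `mz_tolerance`, one-to-one.
#'
#' With fewer than 3 matched pairs the correlation is undefined; `s_int` is
#' then 1.0 when both match fractions are exactly 1 (tiny identical peak
#' sets) and 0.5 (neutral) otherwise. With >= 3 pairs but zero variance on
#' either side, `s_int` is 1.0 when both sides are constant and 0.5 when only
#' one is.
#'
#' @param query A non-empty [peak_list()].
#' @param ref An `msp` reference entry.
#' @param mz_tolerance Matching tolerance in Da (default 2).
#' @param freq_weight Weight the reference match fraction by peak frequency
#'   (default `TRUE`).
#' @return List of class `scored_hit`: `entry_name`, `log_score`, `s_query`,
#'   `s_ref`, `s_int`, `n_matched`.
#' @export
score_spectrum <- function(query, ref, mz_tolerance = 2, freq_weight = TRUE) {
  stopifnot(inherits(ref, "msp"))
  if (!inherits(query, "peak_list")) stop("query must be a peak_list")
  if (!length(query$mz)) stop("no peaks in query spectrum")
  m <- match_peaks(query$mz, ref$peaks$mz, mz_tolerance)
  nm <- nrow(m)
  s_query <- nm / length(query$mz)
  s_ref <- if (freq_weight) {
    if (nm) sum(ref$peaks$frequency[m$ref]) / sum(ref$peaks$frequency) else 0
  } else nm / nrow(ref$peaks)
  s_int <- intensity_agreement(query$intensity[m$query],
                               ref$peaks$intensity[m$ref],
                               s_query, s_ref)
  raw <- 1000 * s_query * s_ref * s_int
  structure(list(entry_name = ref$entry_name,
                 log_score = if (raw <= 1) 0 else log10(raw),
                 s_query = s_query, s_ref = s_ref, s_int = s_int,
                 n_matched = nm),
            class = "scored_hit")
}

# Greedy one-to-one nearest-m/z matching within tolerance. Candidate pairs
# are ranked by |delta m/z|; each query and reference peak is used once.
match_peaks <- function(qmz, rmz, tol) {
  if (!length(qmz) || !length(rmz))
    return(data.frame(query = integer(0), ref = integer(0)))
  pairs <- do.call(rbind, lapply(seq_along(qmz), function(i) {
    j <- which(abs(rmz - qmz[i]) <= tol)
    if (!length(j)) return(NULL)
    data.frame(query = i, ref = j, d = abs(rmz[j] - qmz[i]))
  }))
  if (is.null(pairs))
    return(data.frame(query = integer(0), ref = integer(0)))
  pairs <- pairs[order(pairs$d, pairs$query, pairs$ref), , drop = FALSE]
  used_q <- logical(length(qmz)); used_r <- logical(length(rmz))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    qi <- pairs$query[k]; ri <- pairs$ref[k]
    if (!used_q[qi] && !used_r[ri]) {
      keep[k] <- TRUE; used_q[qi] <- TRUE; used_r[ri] <- TRUE
    }
  }
  pairs[keep, c("query", "ref"), drop = FALSE]
}

intensity_agreement <- function(qi, ri, s_query, s_ref) {
  n <- length(qi)
  if (n < 3L) {
    if (n > 0L && s_query == 1 && s_ref == 1) return(1)
    return(0.5)
  }
  sq <- stats::sd(qi); sr <- stats::sd(ri)
  if (sq == 0 && sr == 0) return(1)
  if (sq == 0 || sr == 0) return(0.5)
  max(0, stats::cor(qi, ri))
}

#' Rank all library entries against a query peak list
#'
#' @param query A non-empty [peak_list()].
#' @param lib A non-empty [spectral_library()].
#' @inheritParams score_spectrum
#' @return data.frame sorted by descending `log_score` (ties broken by entry
#'   name, so ranking is deterministic) with columns `entry_name`,
#'   `log_score`, `s_query`, `s_ref`, `s_int`, `n_matched`.
#' @export
rank_hits <- function(query, lib, mz_tolerance = 2, freq_weight = TRUE) {
  stopifnot(inherits(lib, "spectral_library"))
  if (!length(lib$entries)) stop("spectral library is empty")
  hits <- lapply(lib$entries, function(e)
    score_spectrum(query, e, mz_tolerance, freq_weight))
  df <- data.frame(entry_name = vapply(hits, `[[`, character(1), "entry_name"),
                   log_score = vapply(hits, `[[`, numeric(1), "log_score"),
                   s_query = vapply(hits, `[[`, numeric(1), "s_query"),
                   s_ref = vapply(hits, `[[`, numeric(1), "s_ref"),
                   s_int = vapply(hits, `[[`, numeric(1), "s_int"),
                   n_matched = vapply(hits, `[[`, integer(1), "n_matched"))
  df <- df[order(-df$log_score, df$entry_name), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Replicate-consensus identification call
#'
#' Applies the identification rubric used for real-time classification: an
#' isolate is identified at the species level when at least `min_replicates`
#' biological replicates have the same top-ranked library entry with a log
#' score at or above `threshold` (default 2.2). Failing that, a genus-level
#' call is made when the same condition holds at genus granularity at the
#' (lower) `genus_threshold`. Otherwise the isolate is reported as
#' unidentified / potentially novel. Raising `threshold` can only move calls
#' away from species level, never toward it.
#'
#' @param replicate_hits List (one element per biological replicate) of ranked
#'   hit tables as returned by [rank_hits()].
#' @param threshold Species-level log-score threshold (default 2.2).
#' @param min_replicates Minimum concordant replicates (default 3).
#' @param genus_threshold Genus-level fallback threshold (default 2.0).
#' @param isolate_id Isolate label carried into the call.
#' @return List of class `identification_call`: `isolate_id`, `consensus`
#'   (`"species_level"`, `"genus_level"` or `"unidentified"`), `entry` (the
#'   consensus entry or genus, `NA` if unidentified), `top_scores`,
#'   `top_entries`, `rubric`, `replicate_results`.
#' @export
consensus_call <- function(replicate_hits, threshold = 2.2, min_replicates = 3L,
                           genus_threshold = 2.0, isolate_id = NA_character_) {
  if (!length(replicate_hits)) stop("at least one replicate is required")
  tops <- lapply(replicate_hits, function(h) h[1, , drop = FALSE])
  top_entries <- vapply(tops, `[[`, character(1), "entry_name")
  top_scores <- vapply(tops, `[[`, numeric(1), "log_score")

  consensus <- "unidentified"; entry <- NA_character_
  passing <- top_entries[top_scores >= threshold]
  if (length(passing)) {
    tab <- sort(table(passing), decreasing = TRUE)
    best <- names(tab)[tab == max(tab)]
    cand <- sort(best)[1]
    if (max(tab) >= min_replicates) {
      consensus <- "species_level"; entry <- cand
    }
  }
  if (consensus == "unidentified") {
    genera <- vapply(top_entries, function(e) entry_genus(e), character(1))
    passing_g <- genera[top_scores >= genus_threshold]
    if (length(passing_g)) {
      tab <- sort(table(passing_g), decreasing = TRUE)
      if (max(tab) >= min_replicates) {
        consensus <- "genus_level"
        entry <- sort(names(tab)[tab == max(tab)])[1]
      }
    }
  }
  structure(list(isolate_id = isolate_id,
                 consensus = consensus,
                 entry = entry,
                 top_entries = unname(top_entries),
                 top_scores = unname(top_scores),
                 rubric = list(threshold = threshold,
                               min_replicates = as.integer(min_replicates),
                               genus_threshold = genus_threshold,
                               n_replicates = length(replicate_hits)),
                 replicate_results = replicate_hits),
            class = "identification_call")
}

#' @export
print.identification_call <- function(x, ...) {
  cat(sprintf("identification_call %s: %s%s (top scores: %s)\n",
              x$isolate_id, x$consensus,
              if (!is.na(x$entry)) paste0(" -> ", x$entry) else "",
              paste(sprintf("%.2f", x$top_scores), collapse = ", ")))
  invisible(x)
}

# First whitespace-delimited word of a database entry name, i.e. its genus.
entry_genus <- function(entry_name) strsplit(entry_name, "[ _]")[[1]][1]

#' Identify one isolate from replicate peak lists
#'
#' Ranks each replicate against the library and applies [consensus_call()].
#'
#' @param replicates List of [peak_list()] objects, one per biological
#'   replicate (each replicate's best-scoring acquisition).
#' @param lib A [spectral_library()].
#' @inheritParams consensus_call
#' @inheritParams score_spectrum
#' @return An `identification_call`.
#' @export
identify_isolate <- function(replicates, lib, threshold = 2.2,
                             min_replicates = 3L, genus_threshold = 2.0,
                             mz_tolerance = 2, freq_weight = TRUE,
                             isolate_id = NA_character_) {
  hits <- lapply(replicates, rank_hits, lib = lib,
                 mz_tolerance = mz_tolerance, freq_weight = freq_weight)
  consensus_call(hits, threshold = threshold, min_replicates = min_replicates,
                 genus_threshold = genus_threshold, isolate_id = isolate_id)
}
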
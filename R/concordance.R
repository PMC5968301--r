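#' Taxonomic-group registry
#'
#' Certain sets of species ("taxonomic groups") have nearly identical 16S
#' rRNA sequences and cannot be separated by that marker alone; membership is
#' configuration, not hard-coded biology. The registry shipped with the
#' package contains the two *Bacillus* groups relevant to cleanroom
#' surveillance: the *B. pumilus* group (*pumilus*, *safensis*,
#' *australimaris*, *zhangzhouensis*) and the *B. cereus* group (*cereus*,
#' *thuringiensis*, *anthracis*).
#'
#' @param groups Named list of character vectors of species names
#'   (`"Genus species"`); a species may appear in at most one group.
#' @return Object of class `taxgroup_registry`.
#' @export
taxgroup_registry <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  all_sp <- normalize_species(unlist(groups))
  if (anyDuplicated(all_sp))
    stop("species assigned to more than one taxonomic group: ",
         paste(unique(all_sp[duplicated(all_sp)]), collapse = ", "))
  groups <- lapply(groups, normalize_species)
  structure(list(groups = groups), class = "taxgroup_registry")
}

#' Load a taxonomic-group registry from YAML
#'
#' @param path YAML file mapping group names to species lists. Defaults to
#'   the registry shipped with the package.
#' @export
read_taxgroup_registry <- function(path = system.file("extdata", "taxonomic_groups.yaml",
                                                      package = "msptyper")) {
  obj <- yaml::read_yaml(path)
  taxgroup_registry(lapply(obj$groups, unlist))
}

#' Find the taxonomic group of a species
#' @param registry A [taxgroup_registry()].
#' @param species Species name (any accepted spelling).
#' @return Group name, or `NA` if the species is in no group.
#' @export
taxgroup_of <- function(registry, species) {
  stopifnot(inherits(registry, "taxgroup_registry"))
  for (g in names(registry$groups))
    if (any(vapply(registry$groups[[g]], same_species, logical(1), b = species)))
      return(g)
  NA_character_
}

# Species-name normalization: strips strain suffixes ("_FO36b^T", "_DSM 27^T"),
# type-strain markers and case; keeps "<genus> <epithet>". Genus may be
# abbreviated ("B. safensis"); the abbreviation is preserved as an initial and
# compared compatibly.
normalize_species <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("\\^?T\\^?\\s*$", "", x)              # trailing type-strain marker
  x <- sub("_.*$", "", x)                         # strain suffix after underscore
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

species_epithet <- function(x) {
  parts <- strsplit(normalize_species(x), " ")[[1]]
  if (length(parts) >= 2) parts[length(parts)] else parts[1]
}

species_genus_token <- function(x) {
  parts <- strsplit(normalize_species(x), " ")[[1]]
  if (length(parts) >= 2) sub("\\.$", "", parts[1]) else NA_character_
}

# TRUE when two names denote the same species, allowing an abbreviated genus
# ("b." vs "bacillus") on either side.
same_species <- function(a, b) {
  if (species_epithet(a) != species_epithet(b)) return(FALSE)
  ga <- species_genus_token(a); gb <- species_genus_token(b)
  if (is.na(ga) || is.na(gb)) return(TRUE)
  startsWith(ga, gb) || startsWith(gb, ga)
}

same_genus <- function(a, b) {
  ga <- species_genus_token(a); gb <- species_genus_token(b)
  if (is.na(ga) || is.na(gb)) return(TRUE)
  startsWith(ga, gb) || startsWith(gb, ga)
}

#' Pair a 16S call with a MALDI call and assign a concordance category
#'
#' Applies the rules used to reconcile the two identification methods:
#' \itemize{
#'   \item `genus_only` — the 16S call did not reach species level;
#'   \item `taxgroup_unresolved` — the 16S species belongs to a registered
#'     taxonomic group and the spectral library lacks type-strain entries for
#'     one or more competing group members, so the methods cannot be
#'     reconciled;
#'   \item `potentially_novel` — the MALDI consensus score is below the
#'     identification threshold (default 2.2): the isolate matches no library
#'     entry confidently even though closely related reference spectra are
#'     present;
#'   \item `species_concordant` — both methods name the same species and the
#'     MALDI score passes the threshold;
#'   \item `maldi_confident_discordant` — the names differ but the MALDI
#'     score passes the threshold and the matched entry is a characterized
#'     type strain, so the spectral identification is taken as authoritative.
#' }
#' A genus-level disagreement between the methods is flagged in
#' `genus_mismatch` (it does not occur in practice for concordant archives).
#'
#' @param call_16s A `taxonomy_call`, or a list with `best_ref_id` (species
#'   name), `percent_identity` and `level`.
#' @param call_maldi An `identification_call`, or a list with `entry`
#'   (library entry name) and `top_scores` (or a single `log_score`).
#' @param registry A [taxgroup_registry()].
#' @param threshold MALDI log-score threshold (default 2.2).
#' @param typed_species Character vector of species names for which the
#'   library holds type-strain MSPs; `NULL` (default) means all competing
#'   group members are covered.
#' @param isolate_id Label carried into the record.
#' @return List of class `concordance_record`: `isolate_id`, `category`,
#'   `species_16s`, `species_maldi`, `maldi_score`, `genus_mismatch`.
#' @export
categorize_call <- function(call_16s, call_maldi, registry = read_taxgroup_registry(),
                            threshold = 2.2, typed_species = NULL,
                            isolate_id = NA_character_) {
  sp16 <- call_16s$best_ref_id
  lev16 <- call_16s$level %||% "species"
  entry <- call_maldi$entry
  score <- max(call_maldi$top_scores %||% call_maldi$log_score %||% 0)
  spms <- if (is.null(entry) || is.na(entry)) NA_character_ else entry

  category <- NULL
  if (!identical(lev16, "species")) {
    category <- "genus_only"
  } else {
    grp <- taxgroup_of(registry, sp16)
    if (!is.na(grp) && !is.null(typed_species)) {
      members <- registry$groups[[grp]]
      covered <- normalize_species(typed_species)
      if (!all(members %in% covered)) category <- "taxgroup_unresolved"
    }
  }
  if (is.null(category)) {
    if (score < threshold || is.na(spms)) category <- "potentially_novel"
    else if (same_species(sp16, spms)) category <- "species_concordant"
    else {
      is_type <- call_maldi$is_type_strain %||% grepl("\\^?T\\^?\\s*$", entry)
      category <- if (isTRUE(is_type)) "maldi_confident_discordant"
                  else "potentially_novel"
    }
  }
  genus_mismatch <- !is.na(spms) && !same_genus(sp16, spms)
  if (genus_mismatch)
    warning("genus-level disagreement between methods for isolate ", isolate_id)
  structure(list(isolate_id = isolate_id,
                 category = category,
                 species_16s = sp16,
                 species_maldi = spms,
                 maldi_score = score,
                 genus_mismatch = genus_mismatch),
            class = "concordance_record")
}

#' @export
print.concordance_record <- function(x, ...) {
  cat(sprintf("concordance_record %s: %s (16S=%s, MALDI=%s @ %.2f)\n",
              x$isolate_id, x$category, x$species_16s, x$species_maldi,
              x$maldi_score))
  invisible(x)
}

concordance_categories <- c("species_concordant", "maldi_confident_discordant",
                            "potentially_novel", "taxgroup_unresolved",
                            "genus_only")

#' Tabulate concordance records
#'
#' Counts per category (the categories partition the record set) plus the
#' number of records whose two calls agree at genus level.
#'
#' @param records List of `concordance_record`s.
#' @return List of class `concordance_summary`: `counts` (named integer
#'   vector over all five categories), `n`, `genus_agreement`.
#' @export
tabulate_concordance <- function(records) {
  cats <- vapply(records, `[[`, character(1), "category")
  counts <- table(factor(cats, levels = concordance_categories))
  genus_ok <- sum(!vapply(records, `[[`, logical(1), "genus_mismatch"))
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 n = length(records),
                 genus_agreement = genus_ok),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("concordance_summary: %d isolates\n", x$n))
  for (k in names(x$counts)) cat(sprintf("  %-28s %d\n", k, x$counts[[k]]))
  cat(sprintf("  genus-level agreement: %d of %d\n", x$genus_agreement, x$n))
  invisible(x)
}

#' Run the concordance stage from call tables
#'
#' Convenience wrapper taking a data.frame of per-isolate paired calls (as
#' exported by the 16S and identification stages, or the published
#' comparative table shipped in `extdata`) with columns `isolate`, `id_16s`,
#' `pct_identity`, `id_maldi`, `log_score`.
#'
#' @param calls data.frame of paired calls.
#' @param registry A [taxgroup_registry()].
#' @inheritParams categorize_call
#' @return List with `records` and `summary`.
#' @export
concordance_from_table <- function(calls, registry = read_taxgroup_registry(),
                                   threshold = 2.2, typed_species = NULL) {
  needed <- c("isolate", "id_16s", "pct_identity", "id_maldi", "log_score")
  if (!all(needed %in% names(calls)))
    stop("call table must have columns: ", paste(needed, collapse = ", "))
  records <- lapply(seq_len(nrow(calls)), function(i) {
    categorize_call(
      call_16s = list(best_ref_id = calls$id_16s[i],
                      percent_identity = calls$pct_identity[i],
                      level = if (calls$pct_identity[i] >= 98.7) "species"
                              else if (calls$pct_identity[i] > 95) "genus"
                              else "unclassified"),
      call_maldi = list(entry = calls$id_maldi[i],
                        top_scores = calls$log_score[i]),
      registry = registry, threshold = threshold,
      typed_species = typed_species, isolate_id = calls$isolate[i])
  })
  list(records = records, summary = tabulate_concordance(records))
}

#' Published comparative identification table for the B. pumilus group
#'
#' Ten archived cleanroom isolates from the *Bacillus pumilus* taxonomic
#' group with their 16S rRNA identification (best type-strain match and
#' percent identity) and MALDI-TOF real-time-classification identification
#' (library entry and log score). This is the worked example distributed
#' with the package for exercising the concordance rules.
#'
#' @return data.frame with columns `isolate`, `accession`, `id_16s`,
#'   `pct_identity`, `id_maldi`, `log_score`.
#' @export
pumilus_group_calls <- function() {
  path <- system.file("extdata", "pumilus_group_isolates.tsv", package = "msptyper")
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
}
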
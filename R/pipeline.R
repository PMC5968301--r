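#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end workflow with its
#' standard default: database entries need at least 10 contributing spectra
#' with peak frequency strictly above 0.75 and self-scores above 2.7;
#' identification requires log scores of at least 2.2 on the same top entry
#' in at least 3 of 4 biological replicates; strain comparison uses a
#' 10-interval CCI over 3,000-12,000 m/z; the 16S layer uses 99% OTUs and
#' the 98.7/95 species/genus identity thresholds. The resolved configuration
#' is embedded in every report for provenance.
#'
#' @param scenario A [scenario_config()] describing the simulated study.
#' @param min_spectra,freq_floor,self_score Database-construction settings.
#' @param id_threshold,min_replicates,genus_threshold Identification rubric.
#' @param mz_tolerance Peak-matching tolerance in Da.
#' @param snr,peak_min_mz,peak_max_mz Peak-picking settings.
#' @param cci_intervals,cci_mass_lo,cci_mass_hi,cci_bin_width CCI settings.
#' @param otu_similarity,species_identity,genus_identity 16S settings.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            min_spectra = 10L, freq_floor = 0.75,
                            self_score = 2.7,
                            id_threshold = 2.2, min_replicates = 3L,
                            genus_threshold = 2.0,
                            mz_tolerance = 2, snr = 3,
                            peak_min_mz = 2000, peak_max_mz = 20000,
                            cci_intervals = 10L, cci_mass_lo = 3000,
                            cci_mass_hi = 12000, cci_bin_width = 3,
                            otu_similarity = 0.99, species_identity = 98.7,
                            genus_identity = 95) {
  stopifnot(freq_floor >= 0, freq_floor < 1,
            id_threshold >= 0, id_threshold <= 3,
            self_score >= 0, self_score <= 3,
            otu_similarity > 0, otu_similarity <= 1,
            species_identity > genus_identity)
  structure(as.list(environment()), class = "pipeline_config")
}

# Cohort-level quality control: shared binned grid, one correlation matrix.
# Returns a logical vector marking spectra that pass both checks.
qc_cohort_pass <- function(spectra, min_peaks = 10L, dynamic_floor = 0.01,
                           cor_cutoff = 0.5, snr = 3) {
  n <- length(spectra)
  same_grid <- all(vapply(spectra, function(s)
    length(s$mz) == length(spectra[[1]]$mz) &&
      isTRUE(all.equal(s$mz, spectra[[1]]$mz)), logical(1)))
  M <- if (same_grid) {
    vapply(spectra, `[[`, numeric(length(spectra[[1]]$intensity)), "intensity")
  } else {
    grid <- profile_grid(spectra)
    vapply(spectra, binned_trace, numeric(length(grid) - 1L), edges = grid)
  }
  flat <- vapply(seq_len(n), function(i) {
    s <- spectra[[i]]
    mx <- max(s$intensity)
    dyn <- if (mx > 0) (mx - min(s$intensity)) / mx else 0
    if (dyn < dynamic_floor) return(TRUE)
    length(detect_peaks(s, snr = snr, min_mz = min(s$mz),
                        max_mz = max(s$mz))) < min_peaks
  }, logical(1))
  outlier <- rep(FALSE, n)
  if (n > 1L) {
    sds <- apply(M, 2, stats::sd)
    C <- suppressWarnings(stats::cor(M))
    C[is.na(C)] <- 0
    mean_cor <- (colSums(C) - 1) / (n - 1)
    mean_cor[sds == 0] <- 0
    outlier <- mean_cor < cor_cutoff
  }
  !(flat | outlier)
}

#' Run the full workflow on a synthetic study
#'
#' Orchestrates every stage: scenario simulation, spectral preprocessing and
#' replicate quality control, database (MSP) construction with self-score
#' validation, identification of the unknown isolates with the
#' replicate-consensus rubric, strain-level CCI analysis, the MSP
#' dendrogram, the 16S layer (taxonomy calls, OTU clustering,
#' neighbor-joining tree) and the concordance tabulation between the two
#' identification methods. All randomness derives from the scenario seed, so
#' a rerun with the same configuration reproduces every number.
#'
#' @param config A [pipeline_config()].
#' @param scenario Optional pre-built [build_scenario()] result; defaults to
#'   building one from `config$scenario`.
#' @param out_dir Optional directory for TSV/JSON/newick reports.
#' @param registry A [taxgroup_registry()].
#' @return List of class `pipeline_result` with elements `config`,
#'   `library`, `validation`, `calls`, `recovery`, `cci`, `dendrogram`,
#'   `taxonomy`, `otus`, `tree_16s`, `concordance`, `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), scenario = NULL,
                         out_dir = NULL, registry = read_taxgroup_registry()) {
  stopifnot(inherits(config, "pipeline_config"))
  scen <- scenario %||% build_scenario(config$scenario)

  preprocess_all <- function(spectra) lapply(spectra, function(s) {
    s <- subtract_baseline(s)
    smooth_spectrum(s)
  })
  pick_all <- function(spectra) lapply(spectra, detect_peaks, snr = config$snr,
                                       min_mz = config$peak_min_mz,
                                       max_mz = config$peak_max_mz)

  # --- database construction with replicate QC ------------------------------
  entries <- list(); validation <- list()
  for (sp in names(scen$msp_spectra)) {
    pre <- preprocess_all(scen$msp_spectra[[sp]])
    ok <- qc_cohort_pass(pre, snr = config$snr)
    kept <- pick_all(pre[ok])
    kept <- Filter(length, kept)
    rebuild <- function(reps) build_msp(
      reps, entry_name = paste0(sp, "_T"),
      mz_tolerance = config$mz_tolerance,
      freq_floor = config$freq_floor,
      min_spectra = config$min_spectra,
      taxon = list(genus = strsplit(sp, " ")[[1]][1],
                   species = sp, strain = "type"),
      is_type_strain = TRUE)
    msp <- rebuild(kept)
    val <- validate_msp(msp, kept, threshold = config$self_score,
                        mz_tolerance = config$mz_tolerance)
    # curation loop: spectra that fail the self-score stringency are removed
    # from the entry and the consensus rebuilt, while enough spectra remain
    for (round in 1:2) {
      if (val$all_pass) break
      pass <- val$per_spectrum_scores$log_score > config$self_score
      if (sum(pass) < config$min_spectra) break
      kept <- kept[pass]
      msp <- rebuild(kept)
      val <- validate_msp(msp, kept, threshold = config$self_score,
                          mz_tolerance = config$mz_tolerance)
    }
    entries[[sp]] <- msp
    validation[[sp]] <- val
  }
  lib <- spectral_library(unname(entries))

  # --- identification of unknowns -------------------------------------------
  calls <- lapply(names(scen$unknown_spectra), function(iso) {
    peaks <- pick_all(preprocess_all(scen$unknown_spectra[[iso]]))
    peaks <- Filter(length, peaks)
    identify_isolate(peaks, lib, threshold = config$id_threshold,
                     min_replicates = config$min_replicates,
                     genus_threshold = config$genus_threshold,
                     mz_tolerance = config$mz_tolerance,
                     isolate_id = iso)
  })
  names(calls) <- names(scen$unknown_spectra)

  truth <- scen$truth
  correct <- vapply(seq_len(nrow(truth)), function(i) {
    call <- calls[[truth$isolate[i]]]
    if (truth$in_library[i]) {
      call$consensus == "species_level" &&
        same_species(call$entry, truth$species[i])
    } else {
      call$consensus != "species_level"
    }
  }, logical(1))
  recovery <- list(
    in_library_correct = mean(correct[truth$in_library]),
    novel_unidentified = if (any(!truth$in_library))
      mean(correct[!truth$in_library]) else NA_real_,
    n_in_library = sum(truth$in_library),
    n_novel = sum(!truth$in_library))

  # --- strain-level CCI and spectral dendrogram -----------------------------
  strain_peaks <- lapply(scen$strain_spectra, function(reps)
    Filter(length, pick_all(preprocess_all(reps))))
  cci_res <- cci_matrix(strain_peaks, mass_lo = config$cci_mass_lo,
                        mass_hi = config$cci_mass_hi,
                        bin_width = config$cci_bin_width,
                        n_intervals = config$cci_intervals)
  dend <- msp_dendrogram(lib, mass_lo = config$cci_mass_lo,
                         mass_hi = config$cci_mass_hi,
                         bin_width = config$cci_bin_width)

  # --- 16S layer -------------------------------------------------------------
  taxonomy <- lapply(seq_len(nrow(truth)), function(i) {
    classify_16s(scen$sequences_16s[[truth$species[i]]], scen$references_16s,
                 query_id = truth$isolate[i],
                 species_threshold = config$species_identity,
                 genus_threshold = config$genus_identity)
  })
  names(taxonomy) <- truth$isolate
  otus <- cluster_otus(scen$sequences_16s[truth$species], config$otu_similarity)
  tree <- nj_tree(otus$distances)

  # --- concordance ------------------------------------------------------------
  typed <- names(scen$fingerprints)
  records <- lapply(truth$isolate, function(iso)
    categorize_call(taxonomy[[iso]], calls[[iso]], registry = registry,
                    threshold = config$id_threshold, typed_species = typed,
                    isolate_id = iso))
  conc <- tabulate_concordance(records)

  summary <- list(
    n_entries = length(lib),
    all_msp_validated = all(vapply(validation, `[[`, logical(1), "all_pass")),
    recovery = recovery,
    concordance = conc$counts,
    seed = config$scenario$seed)

  res <- structure(list(config = config, library = lib,
                        validation = validation, calls = calls,
                        recovery = recovery, cci = cci_res,
                        dendrogram = dend, taxonomy = taxonomy, otus = otus,
                        tree_16s = tree,
                        concordance = list(records = records, summary = conc),
                        summary = summary),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_reports(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  library entries:        %d (all self-validated: %s)\n",
              x$summary$n_entries, x$summary$all_msp_validated))
  cat(sprintf("  in-library recovery:    %.1f%% of %d unknowns\n",
              100 * x$recovery$in_library_correct, x$recovery$n_in_library))
  if (!is.na(x$recovery$novel_unidentified))
    cat(sprintf("  novel unidentified:     %.1f%% of %d unknowns\n",
                100 * x$recovery$novel_unidentified, x$recovery$n_novel))
  cat(sprintf("  OTUs:                   %d\n", length(x$otus$clusters)))
  cat("  concordance: ", paste(names(x$summary$concordance),
                               x$summary$concordance, sep = "=",
                               collapse = ", "), "\n")
  invisible(x)
}

write_pipeline_reports <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_library(res$library, file.path(out_dir, "library.json"))
  calls_df <- do.call(rbind, lapply(res$calls, function(c)
    data.frame(isolate = c$isolate_id, consensus = c$consensus,
               entry = c$entry %||% NA_character_,
               top_scores = paste(sprintf("%.3f", c$top_scores), collapse = ";"))))
  utils::write.table(calls_df, file.path(out_dir, "identifications.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(res$cci$values),
                     file.path(out_dir, "cci_matrix.tsv"),
                     sep = "\t", row.names = TRUE, quote = FALSE)
  writeLines(res$dendrogram$newick, file.path(out_dir, "msp_dendrogram.nwk"))
  writeLines(res$tree_16s$newick, file.path(out_dir, "tree_16s.nwk"))
  tax_df <- do.call(rbind, lapply(res$taxonomy, function(t)
    data.frame(isolate = t$query_id, best_ref = t$best_ref_id,
               identity = t$percent_identity, level = t$level)))
  utils::write.table(tax_df, file.path(out_dir, "taxonomy_16s.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  conc_df <- do.call(rbind, lapply(res$concordance$records, function(r)
    data.frame(isolate = r$isolate_id, category = r$category,
               species_16s = r$species_16s, species_maldi = r$species_maldi,
               maldi_score = r$maldi_score)))
  utils::write.table(conc_df, file.path(out_dir, "concordance.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- res$config
  cfg$scenario <- unclass(cfg$scenario)
  cfg$scenario$noise <- unclass(cfg$scenario$noise)
  jsonlite::write_json(list(summary = res$summary, config = unclass(cfg)),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
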
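#' Evaluate an expression under a temporary RNG seed
#'
#' Used by every generator so that simulated objects are pure functions of
#' (parameters, seed); the caller's RNG state is restored afterwards. A
#' `NULL` seed uses (and advances) the current RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a latent species fingerprint
#'
#' A fingerprint is the generative stand-in for a strain's proteomic peak
#' pattern: peak positions drawn uniformly over the analyzed mass range with
#' a minimum spacing of three peak widths (so rendered peaks stay resolved),
#' base intensities, and a per-peak occurrence probability that models
#' replicate-to-replicate peak dropout.
#'
#' @param n_peaks Number of peaks (default 30).
#' @param species Species label.
#' @param mass_range Mass range in Da (default 2000-20000).
#' @param peak_width Gaussian peak sigma in Da used when rendering
#'   (default 3); minimum peak spacing is `3 * peak_width`.
#' @param intensity_range Range of base intensities (default 0.2-1).
#' @param occurrence_range Range of per-peak occurrence probabilities
#'   (default 0.85-1, i.e. frequent enough to survive the MSP frequency
#'   filter).
#' @param seed Integer seed or `NULL`.
#' @return Object of class `fingerprint`: `species`, `peak_mz`,
#'   `base_intensity`, `occurrence_prob`, `peak_width`, `mass_range`.
#' @export
make_fingerprint <- function(n_peaks = 30L, species = "species",
                             mass_range = c(2000, 20000), peak_width = 3,
                             intensity_range = c(0.2, 1),
                             occurrence_range = c(0.85, 1), seed = NULL) {
  n_peaks <- as.integer(n_peaks)
  if (n_peaks < 1L) stop("n_peaks must be >= 1")
  spacing <- 3 * peak_width
  if (n_peaks * spacing > diff(mass_range))
    stop("infeasible peak spacing: too many peaks for the mass range")
  with_seed(seed, {
    mz <- numeric(0)
    tries <- 0L
    while (length(mz) < n_peaks) {
      cand <- stats::runif(n_peaks, mass_range[1], mass_range[2])
      mz <- sort(unique(c(mz, cand)))
      # enforce minimum spacing greedily
      keep <- c(TRUE, diff(mz) >= spacing)
      while (!all(keep)) { mz <- mz[keep]; keep <- c(TRUE, diff(mz) >= spacing) }
      tries <- tries + 1L
      if (tries > 200L) stop("infeasible peak spacing: placement did not converge")
    }
    mz <- sort(sample(mz, n_peaks))
    structure(list(species = as.character(species),
                   peak_mz = mz,
                   base_intensity = stats::runif(n_peaks, intensity_range[1],
                                                 intensity_range[2]),
                   occurrence_prob = stats::runif(n_peaks, occurrence_range[1],
                                                  occurrence_range[2]),
                   peak_width = peak_width,
                   mass_range = mass_range),
              class = "fingerprint")
  })
}

#' Derive a strain variant from a parent fingerprint
#'
#' Applies `n_changes` random edits (peak additions, removals or intensity
#' shifts, chosen with equal probability) to the parent; all other peaks are
#' inherited unchanged, so strains of one species share most of their
#' fingerprint — the structure that strain-level spectral comparison
#' resolves while the species' marker gene cannot.
#'
#' @param parent A [make_fingerprint()] object.
#' @param n_changes Number of edits; must be smaller than the number of
#'   parent peaks.
#' @param strain Strain label appended to the species name.
#' @param seed Integer seed or `NULL`.
#' @return A `fingerprint`.
#' @export
derive_strain <- function(parent, n_changes, strain = "strain", seed = NULL) {
  stopifnot(inherits(parent, "fingerprint"))
  n_changes <- as.integer(n_changes)
  if (n_changes >= length(parent$peak_mz))
    stop("n_changes must be smaller than the number of parent peaks")
  out <- parent
  out$species <- paste0(parent$species, "/", strain)
  if (n_changes == 0L) return(out)
  with_seed(seed, {
    for (k in seq_len(n_changes)) {
      op <- sample(c("add", "remove", "shift"), 1L)
      if (op == "remove" && length(out$peak_mz) > 3L) {
        i <- sample.int(length(out$peak_mz), 1L)
        out$peak_mz <- out$peak_mz[-i]
        out$base_intensity <- out$base_intensity[-i]
        out$occurrence_prob <- out$occurrence_prob[-i]
      } else if (op == "shift") {
        i <- sample.int(length(out$peak_mz), 1L)
        out$base_intensity[i] <- max(0.05, min(1, out$base_intensity[i] *
                                                 stats::rlnorm(1, 0, 0.5)))
      } else {
        spacing <- 3 * out$peak_width
        for (try in 1:50) {
          cand <- stats::runif(1, out$mass_range[1], out$mass_range[2])
          if (all(abs(out$peak_mz - cand) >= spacing)) {
            o <- order(c(out$peak_mz, cand))
            out$peak_mz <- c(out$peak_mz, cand)[o]
            out$base_intensity <- c(out$base_intensity,
                                    stats::runif(1, 0.2, 1))[o]
            out$occurrence_prob <- c(out$occurrence_prob,
                                     stats::runif(1, 0.85, 1))[o]
            break
          }
        }
      }
    }
    out
  })
}

#' Noise model for spectrum simulation
#'
#' @param mz_jitter_sd Per-replicate peak-position jitter sd in Da
#'   (default 0.5).
#' @param intensity_cv Log-normal coefficient of variation of peak
#'   intensities (default 0.25).
#' @param baseline_amplitude Amplitude of the smooth exponential baseline in
#'   intensity units (default 100; peak amplitudes scale to 1000).
#' @param noise_sd Additive Gaussian noise sd (default 3).
#' @param peak_width_sd Per-peak width jitter sd in Da (default 0.3).
#' @return List of class `noise_model`.
#' @export
noise_model <- function(mz_jitter_sd = 0.5, intensity_cv = 0.25,
                        baseline_amplitude = 100, noise_sd = 3,
                        peak_width_sd = 0.3) {
  vals <- c(mz_jitter_sd, intensity_cv, baseline_amplitude, noise_sd, peak_width_sd)
  if (any(vals < 0)) stop("noise model parameters must be non-negative")
  structure(list(mz_jitter_sd = mz_jitter_sd, intensity_cv = intensity_cv,
                 baseline_amplitude = baseline_amplitude, noise_sd = noise_sd,
                 peak_width_sd = peak_width_sd),
            class = "noise_model")
}

#' Render one synthetic raw spectrum from a fingerprint
#'
#' Each fingerprint peak is included as a Bernoulli draw with its occurrence
#' probability, rendered as a Gaussian of (jittered) width at a (jittered)
#' position with a log-normally perturbed amplitude; a smooth exponentially
#' decaying baseline and additive Gaussian noise complete the trace. Peak
#' amplitudes are scaled to a nominal 1000 so the default noise model gives
#' high single-peak signal-to-noise, as typical of protein fingerprints of
#' fresh colony material.
#'
#' @param fp A [make_fingerprint()] object.
#' @param noise A [noise_model()].
#' @param grid_spacing Sampling interval in Da (default 1).
#' @param amplitude_scale Intensity units per unit base intensity
#'   (default 1000).
#' @param isolate_id,replicate_id,acquisition_index Metadata for the
#'   resulting spectrum.
#' @param seed Integer seed or `NULL`.
#' @return A [raw_spectrum()].
#' @export
simulate_spectrum <- function(fp, noise = noise_model(), grid_spacing = 1,
                              amplitude_scale = 1000,
                              isolate_id = fp$species, replicate_id = "r1",
                              acquisition_index = 1L, seed = NULL) {
  stopifnot(inherits(fp, "fingerprint"), inherits(noise, "noise_model"))
  with_seed(seed, {
    mz <- seq(fp$mass_range[1], fp$mass_range[2], by = grid_spacing)
    y <- numeric(length(mz))
    present <- stats::runif(length(fp$peak_mz)) <= fp$occurrence_prob
    for (i in which(present)) {
      pos <- fp$peak_mz[i] + stats::rnorm(1, 0, noise$mz_jitter_sd)
      wid <- max(0.5, fp$peak_width + stats::rnorm(1, 0, noise$peak_width_sd))
      amp <- fp$base_intensity[i] * amplitude_scale *
        stats::rlnorm(1, -noise$intensity_cv^2 / 2, noise$intensity_cv)
      lo <- max(1L, floor((pos - 6 * wid - mz[1]) / grid_spacing) + 1L)
      hi <- min(length(mz), ceiling((pos + 6 * wid - mz[1]) / grid_spacing) + 1L)
      if (lo <= hi) {
        idx <- lo:hi
        y[idx] <- y[idx] + amp * exp(-(mz[idx] - pos)^2 / (2 * wid^2))
      }
    }
    if (noise$baseline_amplitude > 0)
      y <- y + noise$baseline_amplitude * exp(-(mz - mz[1]) / 3000)
    if (noise$noise_sd > 0)
      y <- y + stats::rnorm(length(y), 0, noise$noise_sd)
    raw_spectrum(mz, pmax(y, 0), isolate_id = isolate_id,
                 replicate_id = replicate_id,
                 acquisition_index = acquisition_index)
  })
}

#' Simulate related 16S rRNA gene sequences
#'
#' Draws a random ancestor of `ancestor_length` bases and derives one copy
#' per requested divergence, introducing that many substitutions at distinct
#' positions. One substitution on 1,400 bases leaves the pair at about
#' 99.93% identity — the regime of a taxonomic group — while 100
#' substitutions push identity below the genus threshold.
#'
#' @param divergences Named integer vector: substitutions per derived
#'   sequence; names become sequence ids.
#' @param ancestor_length Ancestor length in bases (default 1400).
#' @param seed Integer seed or `NULL`.
#' @return Named character vector of sequences.
#' @export
simulate_16s <- function(divergences, ancestor_length = 1400L, seed = NULL) {
  if (any(divergences < 0)) stop("divergences must be non-negative")
  if (any(divergences > ancestor_length))
    stop("divergence cannot exceed the sequence length")
  if (is.null(names(divergences)))
    names(divergences) <- paste0("seq", seq_along(divergences))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    anc <- sample(bases, ancestor_length, replace = TRUE)
    out <- vapply(divergences, function(k) {
      s <- anc
      if (k > 0) {
        pos <- sample.int(ancestor_length, k)
        for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
      }
      paste(s, collapse = "")
    }, character(1))
    names(out) <- names(divergences)
    out
  })
}

#' Default synthetic study configuration
#'
#' Describes the default simulated study: 20 library species of which four
#' form a taxonomic group (16S sequences within 1-2 substitutions of each
#' other, distinct spectral fingerprints) and one species carries seven
#' strain variants for strain-level CCI analysis; each database entry is
#' built from 8 biological replicates with 3 acquisitions each, unknowns are
#' measured in 4 biological replicates, and a set of out-of-library
#' ("novel") species probes the unidentified call.
#'
#' @param n_species In-library species count (default 20).
#' @param taxgroup_size Species in the near-identical-16S group (default 4).
#' @param n_strains Strain variants of the strain-analysis species
#'   (default 7).
#' @param n_novel Out-of-library unknown species (default 10).
#' @param n_peaks Peaks per fingerprint (default 30).
#' @param msp_spots,msp_acquisitions Replicate design for database entries
#'   (default 8 spots x 3 acquisitions).
#' @param id_replicates Biological replicates per unknown (default 4).
#' @param strain_spectra Spectra per strain for the CCI stage (default 3).
#' @param noise A [noise_model()].
#' @param grid_spacing Sampling interval in Da (default 1).
#' @param seed Master seed (default 20180518).
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(n_species = 20L, taxgroup_size = 4L, n_strains = 7L,
                            n_novel = 10L, n_peaks = 30L,
                            msp_spots = 8L, msp_acquisitions = 3L,
                            id_replicates = 4L, strain_spectra = 3L,
                            noise = noise_model(), grid_spacing = 1,
                            seed = 20180518L) {
  stopifnot(taxgroup_size <= n_species, n_strains >= 2L)
  structure(as.list(environment()), class = "scenario_config")
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
sub_seed <- function(seed, k) as.integer((as.numeric(seed) * 31 + k) %% 2147483647)

#' Build the synthetic study scenario
#'
#' Generates, as a pure function of the configuration (including its seed):
#' species fingerprints, strain variants, raw replicate spectra for database
#' construction, unknown-isolate spectra (including out-of-library species),
#' strain spectra for CCI, 16S sequences for every species plus type-strain
#' references, and a truth table. With `dir` set, everything is also written
#' to disk (CSV spectra, FASTA, TSV truth table and manifest).
#'
#' @param config A [scenario_config()].
#' @param dir Optional output directory for an on-disk fixture set.
#' @return List of class `scenario` with elements `config`, `fingerprints`,
#'   `strain_fingerprints`, `msp_spectra`, `unknown_spectra`,
#'   `strain_spectra`, `sequences_16s`, `references_16s`, `truth`.
#' @export
build_scenario <- function(config = scenario_config(), dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  cf <- config
  species <- sprintf("Bacillus sim%02d", seq_len(cf$n_species))
  novel <- if (cf$n_novel > 0) sprintf("Bacillus nov%02d", seq_len(cf$n_novel))
           else character(0)

  fingerprints <- lapply(seq_along(species), function(i)
    make_fingerprint(cf$n_peaks, species = species[i],
                     seed = sub_seed(cf$seed, i)))
  names(fingerprints) <- species
  novel_fps <- lapply(seq_along(novel), function(i)
    make_fingerprint(cf$n_peaks, species = novel[i],
                     seed = sub_seed(cf$seed, 1000 + i)))
  names(novel_fps) <- novel

  # strain variants of the first species outside the taxonomic group
  strain_parent <- species[cf$taxgroup_size + 1L]
  strain_fps <- lapply(seq_len(cf$n_strains), function(k)
    derive_strain(fingerprints[[strain_parent]], n_changes = 3L,
                  strain = sprintf("st%02d", k),
                  seed = sub_seed(cf$seed, 2000 + k)))
  names(strain_fps) <- vapply(strain_fps, `[[`, character(1), "species")

  # replicate spectra for database construction
  msp_spectra <- lapply(species, function(sp) {
    fp <- fingerprints[[sp]]
    idx <- 0L
    out <- list()
    for (spot in seq_len(cf$msp_spots)) for (acq in seq_len(cf$msp_acquisitions)) {
      idx <- idx + 1L
      out[[idx]] <- simulate_spectrum(
        fp, cf$noise, grid_spacing = cf$grid_spacing,
        isolate_id = sp, replicate_id = sprintf("spot%02d", spot),
        acquisition_index = acq,
        seed = sub_seed(cf$seed, 10000L + 100L * match(sp, species) + idx))
    }
    out
  })
  names(msp_spectra) <- species

  # unknown isolates: one per in-library species plus the novel species
  unknown_species <- c(species, novel)
  unknown_fps <- c(fingerprints, novel_fps)
  unknown_spectra <- lapply(seq_along(unknown_species), function(i) {
    sp <- unknown_species[i]
    lapply(seq_len(cf$id_replicates), function(r)
      simulate_spectrum(unknown_fps[[sp]], cf$noise,
                        grid_spacing = cf$grid_spacing,
                        isolate_id = paste0("unk_", sp),
                        replicate_id = sprintf("rep%d", r),
                        seed = sub_seed(cf$seed, 40000L + 10L * i + r)))
  })
  names(unknown_spectra) <- paste0("unk_", unknown_species)

  strain_spectra <- lapply(names(strain_fps), function(st) {
    lapply(seq_len(cf$strain_spectra), function(r)
      simulate_spectrum(strain_fps[[st]], cf$noise,
                        grid_spacing = cf$grid_spacing,
                        isolate_id = st, replicate_id = sprintf("rep%d", r),
                        seed = sub_seed(cf$seed,
                                        70000L + 10L * match(st, names(strain_fps)) + r)))
  })
  names(strain_spectra) <- names(strain_fps)

  # 16S layer: taxonomic-group members within 1-2 substitutions of a shared
  # ancestor; all other species (and novel species) well separated
  div <- integer(length(species) + length(novel))
  names(div) <- c(species, novel)
  grp <- seq_len(cf$taxgroup_size)
  div[grp] <- seq_len(cf$taxgroup_size) - 1L            # 0,1,2,... substitutions
  div[-grp] <- 120L + 17L * seq_len(length(div) - cf$taxgroup_size)
  seqs <- simulate_16s(div, seed = sub_seed(cf$seed, 90000L))
  references <- seqs[species]
  truth <- data.frame(isolate = names(unknown_spectra),
                      species = unknown_species,
                      in_library = unknown_species %in% species,
                      stringsAsFactors = FALSE)

  scen <- structure(list(config = cf,
                         fingerprints = fingerprints,
                         novel_fingerprints = novel_fps,
                         strain_fingerprints = strain_fps,
                         msp_spectra = msp_spectra,
                         unknown_spectra = unknown_spectra,
                         strain_spectra = strain_spectra,
                         sequences_16s = seqs,
                         references_16s = references,
                         truth = truth),
                    class = "scenario")
  if (!is.null(dir)) write_scenario(scen, dir)
  scen
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(paste0("scenario: %d library species (%d in taxonomic group), ",
                     "%d strains, %d unknowns (%d novel), seed %d\n"),
              x$config$n_species, x$config$taxgroup_size,
              length(x$strain_fingerprints), nrow(x$truth),
              sum(!x$truth$in_library), x$config$seed))
  invisible(x)
}

write_scenario <- function(scen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec_dir <- file.path(dir, "spectra")
  dir.create(spec_dir, showWarnings = FALSE)
  manifest <- character(0)
  safe <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
  for (iso in names(scen$unknown_spectra)) {
    for (s in scen$unknown_spectra[[iso]]) {
      f <- file.path(spec_dir, sprintf("%s_%s.csv", safe(iso), safe(s$replicate_id)))
      write_spectrum_csv(s, f)
      manifest <- c(manifest, f)
    }
  }
  fa <- file.path(dir, "sequences_16s.fasta")
  write_fasta(scen$sequences_16s, fa)
  refs <- file.path(dir, "references_16s.fasta")
  write_fasta(scen$references_16s, refs)
  tt <- file.path(dir, "truth.tsv")
  utils::write.table(scen$truth, tt, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- c(manifest, fa, refs, tt)
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
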
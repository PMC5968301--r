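# Shared in-code fixtures. Everything is generated; nothing binary on disk.

# A peak list with given m/z and intensities (intensities default equal).
pl <- function(mz, intensity = rep(1, length(mz)), ...) {
  peak_list(mz, intensity, ...)
}

# n identical copies of a peak list.
replicate_pl <- function(n, mz, intensity = rep(1, length(mz))) {
  lapply(seq_len(n), function(i) peak_list(mz, intensity))
}

# An MSP built from identical replicates of the given peaks.
simple_msp <- function(mz, intensity = rep(1, length(mz)), name = "entry",
                       n = 10L, ...) {
  build_msp(replicate_pl(n, mz, intensity), entry_name = name, ...)
}

# Small-scenario pipeline result, computed once per test run and reused by
# the acceptance suite (the default study conditions, scaled only in what is
# recomputed, never in its parameters).
default_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(pipeline_config())
    cache
  }
})

# Small synthetic strain set for CCI tests: one parent species, strain
# variants plus an unrelated species, few replicates, coarse grid for speed.
strain_fixture <- function(seed = 7L) {
  parent <- make_fingerprint(20, species = "parent", seed = seed)
  other <- make_fingerprint(20, species = "other", seed = seed + 1L)
  strains <- lapply(1:3, function(k)
    derive_strain(parent, 3, strain = paste0("st", k), seed = seed + 10L + k))
  nm <- noise_model(baseline_amplitude = 0, noise_sd = 0)
  peaks_of <- function(fp, r)
    detect_peaks(simulate_spectrum(fp, nm, seed = seed + 100L + r),
                 snr = 3)
  sets <- c(lapply(strains, function(fp) lapply(1:2, peaks_of, fp = fp)),
            list(lapply(1:2, peaks_of, fp = other)))
  names(sets) <- c(paste0("strain", 1:3), "other")
  sets
}
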
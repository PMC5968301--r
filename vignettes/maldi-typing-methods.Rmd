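---
title: "Methods: custom MALDI-TOF reference libraries and 16S concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: custom MALDI-TOF reference libraries and 16S concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msptyper)
```

## The problem

Whole-cell MALDI-TOF mass spectrometry identifies bacteria by matching the
protein fingerprint of an unknown isolate (mostly ribosomal proteins, in the
2,000–20,000 m/z range for singly charged ions) against a library of
reference *main spectral profiles* (MSPs). Commercial libraries are biased
toward clinical taxa; surveys of specialised environments — spacecraft
assembly cleanrooms being the motivating case — are dominated by
spore-forming *Bacillus* lineages that such libraries cover poorly. The
remedy is a custom library built from the archive itself, validated against
the 16S rRNA identifications that the archive already carries.

`msptyper` implements that whole workflow as open, tested code: spectral
preprocessing and quality control, stringent MSP construction, log-score
classification with a replicate-consensus rubric, composite correlation
index (CCI) analysis for strain-level structure, spectral dendrograms, a 16S
rRNA layer (pairwise identity, taxonomy thresholds, OTU clustering,
neighbor-joining trees) and the concordance tabulation that reconciles the
two methods. A synthetic-data module generates ground-truthed inputs so that
every stage is testable without instrument data.

## Spectral preprocessing

A raw spectrum is a continuous m/z–intensity trace. Three steps produce a
discrete peak list:

* **Baseline subtraction** — SNIP-style iterative clipping: each pass
  replaces every intensity by the minimum of itself and the mean of its
  neighbours at `half_window` points (default 100, i.e. 100 Da on the 1-Da
  grid), repeated `iterations` times (default 30). Constant and linear
  baselines are preserved exactly by the neighbour mean and therefore
  removed in full; features narrower than the window are clipped away. Near
  the trace ends the window shrinks symmetrically, which keeps the neighbour
  mean unbiased on sloping baselines — with one-sided clamping a rising
  baseline is eroded at the boundary and leaks into the recovered signal.
* **Smoothing** — Savitzky–Golay, window 21 points, polynomial order 3
  (conventional values; the instrument-vendor defaults are not published).
  Polynomials up to the order pass through unchanged.
* **Peak picking** — local maxima measured by their height above a wide
  (99-point) running median. A peak is kept when that height exceeds
  `snr` (default 3) times a robust noise estimate — the median absolute
  deviation, scaled to Gaussian sigma, of the residual around the same
  running median — and `rel_floor` (default 1%) of the base-peak height.
  The residual-based noise estimate matters: after smoothing, the noise is
  strongly autocorrelated and a differenced-trace estimate collapses,
  passing thousands of noise wiggles. Peak intensities are normalised to a
  base peak of 1.0, making everything downstream invariant to the absolute
  intensity scale.

Replicate quality control applies the two conventional elimination rules:
*flat-line* spectra (dynamic range below 1% or fewer than 10 detectable
peaks) and *outliers* (mean Pearson correlation to the other cohort members,
on 1-Da binned profiles, below 0.5). The thresholds are configurable; the
named rules are standard but their numeric values are not published, so
these defaults are our own and are stated in every report.

## MSP construction and validation

An MSP is built from at least `min_spectra = 10` replicate peak lists
(default design: 8 biological replicates × 3 acquisitions, QC survivors).
Peaks are pooled and clustered by greedy single-linkage chaining within
`mz_tolerance = 2` Da — the tolerance is our choice, a few hundred ppm in
the 3–12 kDa range, as no matching tolerance is published. Each cluster
keeps its intensity-weighted mean m/z, mean intensity (re-normalised to
base peak 1.0) and *frequency*: the fraction of replicate lists that
contributed to it. Only clusters with frequency **strictly greater than**
`freq_floor = 0.75` survive — the wording of the stringency rule is
"greater than 75%", so exactly 75% is excluded, and the package follows it
literally. The frequency denominator is the contributing peak list (not the
biological spot); this choice is recorded in each entry's provenance.

Every finished entry is validated by scoring each contributing peak list
against it; all must exceed a self-score of 2.7 (on the 0–3 scale below).
In the pipeline, replicates that fail this stringency are removed from the
entry and the consensus is rebuilt while at least `min_spectra` remain —
the curation step implied by requiring each contributing line to pass.

## Log scores and the identification rubric

The commercial scoring function is proprietary; the package uses the widely
described three-component composite and reports all components so the
formula is auditable. With greedy one-to-one nearest-m/z matching within
tolerance:

$$\mathrm{score} = \max\!\left(0,\ \log_{10}\big(1000\, s_q\, s_r\, s_i\big)\right)$$

where \(s_q\) is the matched fraction of query peaks, \(s_r\) the matched
fraction of reference peaks — by default weighted by MSP peak frequency, so
missing an always-present peak costs more than missing a 76%-frequency one —
and \(s_i\) the non-negative Pearson correlation of matched-pair
intensities. Identity scores exactly 3.0 (\(\log_{10} 1000\)); unrelated
peak sets score 0. With fewer than 3 matched pairs the correlation is
undefined and \(s_i\) is 1.0 when both match fractions are 1, else a
neutral 0.5; with zero variance on both sides it is 1.0, on one side 0.5.

An isolate measured in 4 biological replicates is identified at **species
level** when at least 3 replicates have the *same* top-ranked entry with a
score ≥ 2.2 ("consistently" is read as same top entry, since published call
tables report a single entry per isolate). Failing that, a **genus-level**
call requires the same consensus at genus granularity at a threshold of 2.0
(a convention, configurable); otherwise the isolate is
**unidentified / potentially novel**. Ties in ranking are broken
lexicographically for determinism.

## Composite correlation index and dendrograms

For strain-level comparison, profiles are binned into 3-Da half-open bins
over 3,000–12,000 m/z and total-normalised. (The mass window is stated in
the source material as "3,000 and 12,000 kDa"; we read kDa as a typo for
m/z in Da — 12,000 kDa is outside any biotyping range.) The bin range is
split into `n_intervals = 10` contiguous blocks; the CCI of two profiles is
the mean over blocks of the zero-clamped Pearson correlation of their bin
values. Blocks where both profiles are constant (empty mass regions)
contribute 1.0; blocks where only one side is constant contribute 0.0 —
this convention avoids 0/0 and is part of the documented formula. The exact
commercial CCI composition is undocumented; ours matches the printed
semantics (1 identical, 0 uncorrelated, >0.9 strong) and uses own-interval
correlations only, not interval cross-correlations. Replicates of a strain
are averaged (arithmetic mean of normalised binned profiles) before
comparison, with at least two spectra per strain required.

MSP dendrograms are average-linkage (UPGMA) agglomerations of the binned
profiles under Euclidean distance, computed with `stats::hclust` after
sorting entries by label so input order cannot matter; newick branch
lengths follow the ultrametric node heights.

## The 16S rRNA layer

Percent identity is computed from a global Needleman–Wunsch alignment
(match +1, mismatch −1, gap open 2, gap extend 0.5, via Biostrings) as
matches over aligned columns excluding terminal-gap columns; internal gap
columns count against identity. For near-identical ~1.4-kb sequences the
value is insensitive to the scoring parameters. Orientation is checked by
re-aligning against the reverse complement when identity falls below 60%;
the classical flip rule is stated at 50%, but under this identity
definition unrelated sequences already align at ~50–55% (gaps let a quarter
of random columns match), so a 50% trigger never fires — 60% leaves a
margin above that floor while remaining far below any genuinely related
pair.

Taxonomy calls use the conventional full-length 16S thresholds: best
reference ≥ 98.7% identity → species; > 95% → genus; otherwise
unclassified. OTUs are formed by average-linkage clustering of pairwise
distances (1 − identity/100) cut at 1% distance (99% OTUs), each
represented by the member minimising total within-cluster distance (ties by
id) — the minimum-total-distance representative rule. The OTU layer's
"neighbor joining" description in the source methods cannot be mapped to a
documented clustering option of the tool it names (whose methods are
nearest/furthest/average); average linkage is used and the discrepancy
noted here. Trees are built by a hand-implemented neighbor-joining
agglomeration with two conventions: Q-criterion ties broken by the
lexicographically smallest label pair, and negative branch lengths clamped
to zero with the deficit moved to the sister branch, preserving the joined
pair's path length. Maximum-likelihood inference with model selection is
out of scope; neighbor joining covers the comparison actually displayed.

## Concordance between the two methods

Per isolate, the 16S call and the MALDI call are reconciled into five
mutually exclusive categories, in this order of precedence:

1. `genus_only` — the 16S call did not reach species level;
2. `taxgroup_unresolved` — the 16S species belongs to a registered
   *taxonomic group* (a set of species with near-identical 16S, e.g. the
   *B. pumilus* group: *pumilus*, *safensis*, *australimaris*,
   *zhangzhouensis*) and the library lacks type-strain entries for some
   competing member. Group membership is configuration (a YAML registry
   shipped with the package), and the unresolvability is modelled as a
   library-completeness condition, not an intrinsic property of the
   isolate;
3. `potentially_novel` — the MALDI consensus score is below 2.2 despite
   related references being present;
4. `species_concordant` — same species, MALDI score ≥ 2.2;
5. `maldi_confident_discordant` — names differ, MALDI score ≥ 2.2 and the
   matched entry is a characterized type strain, so the spectral call is
   taken as authoritative.

Species names are normalised before comparison (strain suffixes such as
`_FO36b^T` stripped, abbreviated genera matched by initial). A genus-level
disagreement between the methods is flagged separately and warned about; it
does not occur in concordant archives. On the 16S side, "potentially novel"
is interpreted as identity below 98.7% to every reference — the per-isolate
rule is not spelled out in the source and this reading is exposed as
configuration.

## The synthetic study

The generator is a pure function of (configuration, seed). A species is a
*latent fingerprint*: peak positions uniform over 2,000–20,000 m/z with
minimum spacing of three peak widths, base intensities in 0.2–1, and
per-peak occurrence probabilities in 0.85–1 modelling replicate-to-replicate
dropout. A replicate spectrum renders each present peak as a Gaussian
(σ = 3 Da, jittered by 0.3 Da) at a position jittered by 0.5 Da, with
log-normally perturbed amplitude (CV 0.25, nominal base-peak amplitude
1000), on a 1-Da grid with a smooth exponentially decaying baseline
(amplitude 100) and additive Gaussian noise (σ = 3). These are our choices
of a realistic regime — protein peaks of fresh colony material are far
above noise, and dropout rather than noise drives the MSP frequency filter;
no claim of instrument realism (isotope envelopes, detector saturation,
TOF peak shapes) is made. Strains are derived from a parent fingerprint by
a small number of random edits (add/remove/intensity-shift), so strains
share most of their fingerprint. 16S sequences are derived from a random
ancestor with specified substitution counts: group members differ by 1–2
substitutions (≥ 99.9% identity), other species by hundreds.

The default study mirrors the motivating design: 20 library species
including one 4-member taxonomic group and one species with 7 strain
variants; database entries from 8 spots × 3 acquisitions; unknowns in 4
biological replicates (one unknown per library species plus 10
out-of-library species probing the novel-detection path); 2–3 spectra per
strain for the CCI stage. These sizes are the package's default study
conditions and are what the acceptance checks run.

What passing on this synthetic study shows — and does not show: it
validates the *logic* of every stage (frequency filtering, scoring, rubric,
thresholds, concordance arithmetic) under a data-generating process that
satisfies the stages' assumptions by construction. It does not validate
vendor-score comparability on real instrument data (the commercial formula
is undisclosed; only the scale, ceiling, thresholds and rubric semantics
are contracted), nor robustness to real-world artefacts such as matrix
effects or saturation.

## Worked example

```{r example, eval = FALSE}
library(msptyper)

# the published 10-isolate comparison for the B. pumilus taxonomic group
calls <- pumilus_group_calls()
res <- concordance_from_table(calls, threshold = 2.2)
res$summary
#> concordance_summary: 10 isolates
#>   species_concordant           4
#>   maldi_confident_discordant   3
#>   potentially_novel            3
#>   taxgroup_unresolved          0
#>   genus_only                   0
#>   genus-level agreement: 10 of 10

# the full synthetic study (about three minutes on one CPU)
out <- run_pipeline(pipeline_config())
out
#> pipeline_result
#>   library entries:        20 (all self-validated: TRUE)
#>   in-library recovery:    100.0% of 20 unknowns
#>   novel unidentified:     100.0% of 10 unknowns
#>   OTUs:                   27
#>   concordance:  species_concordant=20, ... genus_only=10
```

## Numerical and design notes

* Binning is half-open `[lo, hi)` everywhere, lower bound inclusive, so a
  peak at exactly 3,000 m/z is counted and one at 12,000 is not.
* Duplicate m/z values in raw input are collapsed by summing; unsorted
  input is sorted with intensities carried along.
* The spectral library serialises to versioned JSON (diffable, portable,
  no binary dependency); duplicate entry names and truncated files are
  rejected at load, never returned as partial libraries.
* The mzML support is a minimal standard-conformant subset (one spectrum
  per file, 64-bit little-endian, uncompressed) sufficient for round-trip
  exchange of simulated spectra.
* All stage interfaces are plain R functions returning plain objects, and
  every report embeds the resolved configuration and seed; the
  `run_pipeline()` orchestration plus per-stage functions are the
  command-line surface of this package — its users drive it from R.
* Known limitations: scores are not numerically comparable to vendor
  scores on real data; the 16S layer aligns pairwise rather than against a
  curated reference alignment; chimera checking and ML tree inference are
  out of scope.
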
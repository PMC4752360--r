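---
title: "Acoustic-molecular species delimitation: models and design choices"
author: "songDelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic-molecular species delimitation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songDelim)
```

# The problem

Island cricket faunas hide cryptic diversity: morphologically similar
populations can carry strongly diverged calling songs, and song is the
mating trait across which reproductive isolation is expressed. The
workflow supported here surveys a region acoustically, measures song
traits, standardizes them for temperature, groups them into song types,
asks whether undescribed song types are genetically diverged enough to be
treated as candidate species, interprets the resulting species lists in
an island-biogeographic frame, and quantifies how survey effort
translates into discovered diversity. `songDelim` implements each stage
as a testable unit, together with seeded generators that produce
synthetic inputs with the statistical structure the stages assume.

# Song model and measurement

A calling song is modelled as a train of *sentences*, each containing 1-3
*syllables* (the syllabic pattern: mono-, di-, or trisyllabic); each
syllable is a train of *pulses* -- short tone bursts at the fundamental
frequency. The measured traits are the fundamental (dominant spectral
peak), the syllabic pattern, the onset-to-onset syllable periods P1 and
P2 (where the pattern has a successor syllable), the onset-to-onset
period of sentence repetition, and the within-syllable pulse rate.

Two conventions were genuinely open and are fixed as follows:

* **Periods are onset-to-onset.** Offsets depend on where the decaying
  envelope crosses a threshold, so offset-based periods would inherit
  amplitude-dependent bias; onsets are sharp under any relative
  threshold.
* **Pulse rate of the closest syllable pair.** For di- and trisyllabic
  songs the reported pulse rate is measured on the two syllables of a
  sentence with the smallest onset gap (averaged over the pair); for
  monosyllabic songs it is the mean over syllables. "Closest syllables"
  is not defined operationally anywhere we could find, so this choice is
  documented rather than inherited.

Measurement proceeds by (1) a moving-average envelope of the rectified
signal (default 2 ms window); (2) syllable detection as maximal
supra-threshold runs, with runs separated by gaps under 5 ms merged
(pulse gaps must not split syllables) and runs under 3 ms discarded; the
threshold is 20% of the 95th-percentile envelope amplitude, so all
measurements are invariant to amplitude scaling; (3) sentence grouping at
onset gaps above 150 ms; (4) the fundamental as the peak of a
Hann-windowed, segment-averaged (Welch) periodogram inside a configurable
band, default 2-10 kHz, bracketing the 4-7 kHz range these songs occupy.
All defaults live in one place (`measureConfig()`) and are tuned to the
synthesizer's defaults; they are starting points, not field-proof
settings.

One degenerate case deserves a rule: an unbroken tone produces a single
supra-threshold interval spanning the recording. A syllable must be
bounded by sub-threshold gaps, so a lone interval covering at least 95%
of the recording is reported as "no syllables" (with the fundamental
still measured).

# Temperature standardization

Acoustic traits of ectotherms drift with temperature, so all recordings
are referred to a 22 °C equivalent using linear standard curves with
slopes: fundamental +120 Hz·°C⁻¹, pulse rate +0.4 pulses·s⁻¹·°C⁻¹, and
durations +2.5 %·°C⁻¹. Frequency and pulse rate are corrected additively
(`x22 = x - c·(T-22)`); durations and periods multiplicatively
(`x22 = x / (1 + 0.025·(T-22))`), the natural reading of a percent slope.
Corrections are only accepted inside the 20-29 °C window for which the
curves are intended. The stated slopes are *increases* with temperature;
the positive duration slope (slower songs when warmer) is physiologically
surprising, and the coefficients are therefore user-configurable
(`tempCoefficients()`), with the defaults implemented exactly as stated.
`fitStandardCurve()` recovers per-trait slopes from repeated recordings
of one individual at two or more temperatures by ordinary least squares,
reporting duration slopes as percent per degree relative to the fitted
22 °C value.

The synthesizer applies the same model forward, which gives the key
invariant the tests exploit: *correct-to-22 after measure after
synthesize-at-T is the identity* on the 22 °C specification, up to
measurement error.

# Song typing

Song types are recovered by K-means within each syllabic-pattern stratum
(period columns are only comparable within a pattern). Features are
z-scored by default -- the table mixes Hz and ms scales, and unscaled
K-means would be dominated by frequency. Clustering uses base R's
`kmeans` (Lloyd iterations) with 50 random restarts under a fixed seed,
keeping the best (lowest-inertia) solution; we use random restarts rather
than k-means++ seeding because the restart count, not the seeding rule,
carries the best-of-restarts contract that is actually tested. Cluster
labels are 1-based, following R convention. When no a-priori (aural)
group count is available, `selectK()` picks k by maximum mean silhouette
width over a candidate range and returns the full silhouette/inertia
profile, so a structureless table is visible as a flat, low profile
rather than a silent arbitrary k. Agreement with aural labels is
quantified by the adjusted Rand index plus an exact-match flag
(identity up to label permutation).

# Divergence thresholding

Genetic divergence is deliberately simple: the substitution count *d*
between two aligned sequences (positions where both characters are
unambiguous bases and differ) and the percent "absolute divergence"
`D = 100·d/L` on the full alignment length *L* -- an uncorrected
p-distance. Positions with a gap or N in either sequence never count as
substitutions but stay in the denominator; this fixed-*L* convention is
the one consistent with quoting counts and percentages in pairs (e.g. 14
substitutions on 1594 bp as 0.88%), and it is flagged as a caveat for
gappy alignments. Reported values use two decimals below 1% and one
decimal above; the unrounded value is always available.

The delimitation rule: the threshold θ is the *minimum* divergence
between described species (over described-described group pairs, each
summarized by its cross-pair minimum); an undescribed group is flagged as
a putative species iff its minimum divergence to its closest group
*strictly exceeds* θ ("exceeds" is read as a strict inequality, so a
group exactly at θ is not flagged). Divergences at or below θ fall inside
the observed intraspecific range and are reported as such. p-distances
after gap masking need not satisfy the triangle inequality; nothing here
assumes they do.

# Phylogenetic biogeography

Given a rooted species-labelled tree, three questions are answered
topologically:

* **Monophyly** of a tip set (`isMonophyletic()`), the predicate behind
  discriminating single-colonization (cladogenesis) from
  multiple-colonization scenarios. Likelihood-based topology tests are
  out of scope; unrooted trees are refused rather than silently rooted.
* **Minimum host-association shifts** by Fitch small parsimony
  (`fitchMinChanges()`): one postorder pass, counting empty
  intersections of child state sets. Implemented directly (it is the
  quantity of interest), and cross-checked in the tests against both an
  exhaustive enumeration of ancestral assignments and an independent
  parsimony implementation.
* **Immigrant / anagenetic / cladogenetic classification** per
  archipelago: species in a maximal archipelago-endemic clade of two or
  more species are cladogenetic; archipelago-endemic species whose
  sister lineage lies outside are anagenetic; a species shared between
  archipelagos is immigrant in the recipient archipelago(s) and
  anagenetic in the source, with the direction supplied by an explicit
  colonization scenario (younger-from-older or the reverse). Conspecific
  tips are collapsed to one per species first, so dense within-species
  sampling cannot inflate cladogenesis counts. The immigrant-vs-
  anagenetic boundary (how much divergence turns an immigrant into an
  anagenetic species) is not formalized here; the classifier follows the
  operational pattern that shared species are immigrants in the
  recipient, and this is a modelling choice, not a measurement.

`radiationSummary()` joins the categories with archipelago area and
isolation for comparison against radiation-zone predictions (cladogenesis
expected only on large, isolated archipelagos). The bundled reference
dataset (`exampleRegionalTree()` and friends) encodes the western Indian
Ocean *Ornebius* fauna: the topology is fixed by the regional clade
structure (a monophyletic six-species Mascarene clade; the Comoros pair
sister to *O. syrticus*; *O. validus* outside the main regional clade;
song type 10 closest to *O. luteicercis*; *Pandanus*-associated lineages
non-monophyletic), while branch lengths are synthetic and illustrative.
Farquhar is grouped with the Aldabra Group in the occurrence table; the
area/isolation values are approximate compilations.

# Discovery curves

Cumulative first detections are modelled as
`N(t) = Nspmax / (1 + (t/t50)^b)` with b < 0: `Nspmax` is the asymptotic
species number, `t50` the nights needed to find half of them, and `b`
the steepness. Fitting is Levenberg-Marquardt nonlinear least squares
(`minpack.lm::nlsLM`) from the deterministic start
(max N, median t, b = -2) with `Nspmax` bounded in (0, 10·max N]; no
randomness is involved. Fit quality "R" is the Pearson correlation
between observed and fitted counts (R² is also kept) -- reported this
way because the quantity is conventionally printed without a definition.
When several regions are surveyed on different calendars, their curves
are pooled by aligning each region's night index at 1 and summing the
per-region cumulative counts at each night; this pooling semantics is
recorded here because "pooled on the same time scale" admits
alternatives. `logisticFraction(t, t50, b)` evaluates the curve scaled
to its asymptote; at the reference parameters (t50 = 3.46, b = -2.83) it
yields 0.993 at t = 20 and 0.996 at t = 24 nights.

# Synthetic data: what it emulates, and what it does not

The generators define the study conditions for all tests:

* **Songs** (`synthesizeSong()`): pulse micro-structure inside a syllable
  is nowhere described for these crickets, so a syllable is modelled as
  k = round(pulse rate × duration) tone bursts at 50% duty cycle with
  raised-cosine ramps -- a stand-in chosen to give unambiguous envelope
  peaks, not a claim about stridulation mechanics. The carrier is
  phase-continuous and gated by the burst envelope, which keeps the
  dominant spectral line exactly at the fundamental instead of snapping
  to a pulse-repetition comb line. Defaults (5 kHz fundamental, 40 ms
  syllables at 250 pulses·s⁻¹, 500 ms sentence period) are plausible for
  the group and compatible with the detector defaults. Noise is additive
  white Gaussian at configurable RMS. No attempt is made to mimic real
  spectral timbre, reverberation, overlapping singers, or microphone
  responses -- so passing round-trip tests demonstrates internal
  consistency of the measurement chain, not field robustness.
* **Alignments** (`simulateAlignment()`): Jukes-Cantor along a known
  tree at the 1594 bp mitochondrial scale. The divergence stage consumes
  raw substitution counts, which JC suffices to exercise; richer models
  (GTR+I+G) and indels are out of scope.
* **Feature tables** (`generateSongParameterTable()`): Gaussian groups
  with known labels; separations of 6-10 pooled SDs make exact K-means
  recovery a near-certain event, which is what the recovery tests
  assert.
* **Survey histories** (`generateSurveyHistory()`): first-detection
  times drawn by inverting the logistic curve (iid draws, or noiseless
  quantile placement for exact half-pool checks), with integer nights as
  ceilings of the continuous times. Defaults are 11 species, t50 = 3.46,
  b = -2.83 over 40 nights.

All generators are bit-reproducible under a fixed seed.

# Numerical choices and problem sizes

Tolerances asserted in the test suite follow the error sources: pattern
and counts exact; periods within 2 ms (onset quantization plus envelope
ramps); fundamental within one periodogram bin (sampleRate/8192 ≈ 5.4 Hz
at 44.1 kHz); noiseless logistic parameter recovery within 0.1%;
JC p-distances within three binomial standard errors. Test problem sizes
are deliberately desk-scale -- a few seconds of audio per round trip,
alignments up to 50 × 2000 for oracle equivalence, 10 000 bp pairs for
JC expectations, 60-100 seeded replicates for the stochastic recovery
checks -- chosen so the whole suite exercises every contract in well
under a minute of compute while keeping Monte-Carlo margins comfortable.

# Known limitations

* The song measurement chain assumes a single singer; duetting and
  chorus recordings are out of scope.
* The divergence stage uses uncorrected distances with a fixed
  denominator; model-corrected distances and coalescent-based
  delimitation are deliberately not implemented.
* The biogeographic classifier encodes the operational rules described
  above; it does not infer ancestral ranges or dates.
* WAV support covers uncompressed PCM16/float32 mono and stereo only.
* The user-facing interfaces are R functions; there is no shell CLI.
  Scripts composing the exported functions (see `scripts/acceptance.R`)
  are the intended automation route.
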
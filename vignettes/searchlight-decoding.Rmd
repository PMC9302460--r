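---
title: "Spatiotemporal searchlight decoding of MEG sensor data: methods and design"
author: "megmvpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal searchlight decoding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `megmvpa`, the
choices made where a published analysis leaves details open, and what the
synthetic-data tests do and do not establish about real recordings.

## The analysis in one paragraph

Given epoched multichannel data (trials × channels × samples), a planar
sensor layout and per-trial class labels, the pipeline asks, for every
(channel, time) cell, how well the labels can be decoded from the local
spatiotemporal response pattern, standardizes that accuracy against an
empirical within-subject chance distribution, and tests at the group
level where and when decoding exceeds chance, correcting for the
thousands of simultaneous cells by cluster-based permutation. Its
scientific use case is the time course of word production: object
category (conceptual preparation), word length in syllables
(syllabification load), and phonological neighborhood density
(phonetic encoding) as successive decodable properties of picture-naming
epochs.

## Preprocessing

**Bandpass and decimation.** `bandpassDownsample()` applies a 4th-order
Butterworth bandpass (defaults 1–30 Hz) with `signal::filtfilt`, i.e.
zero-phase with the attenuation applied twice, then keeps every *k*-th
sample where *k* = `fs / targetFs` must be an integer (1200 Hz → 300 Hz
is *k* = 4). The filter order and type are a documented choice; the
source analyses state only the band. Missing samples are zeroed before
filtering and tracked through the mask instead: a decimated cell is
missing if *any* source sample in its block was missing. This is
deliberately conservative — contaminated samples never contribute to a
feature, at the cost of discarding a few clean neighbors.

**Synthetic planar gradients.** Axial gradiometers produce bipolar field
patterns around a source, which makes sensor-level maps hard to read.
`planarGradient()` estimates the two tangential derivatives at each
channel from its first-order neighbor differences by weighted least
squares: with neighbor offsets $d_j = p_j - p_i$ and weights
$w_j = 1/\lVert d_j\rVert^2$, the gradient solves
$\min_g \sum_j w_j \,((F_j - F_i) - g^\top d_j)^2$. This operator is
linear in the field and *exact* for spatially linear fields (a unit test
pins both properties); a rank-deficient neighbor geometry (collinear
neighbors) falls back to the pseudoinverse, estimating only the component
along the available direction. The source analyses name only
"nearest-neighbor interpolation"; the weighting here is the documented
concrete choice, covered by the linear-field oracle. `combinePlanar()`
returns $\sqrt{h^2 + v^2}$ per sample — non-negative,
rotation-invariant, maximal above the source. A channel's components are
missing wherever the channel or any neighbor is missing, and combined
cells inherit that.

## Searchlight geometry

A searchlight at (channel, time) collects the channel's first-order
neighbors — by default including the center — over a 150 ms window:
`round(150 × fs / 1000)` = 45 samples at 300 Hz, flattened channel-major.
A 10-channel set therefore yields 450 features, a 4-channel set 180.
Two conventions were genuinely open:

- **Center inclusion.** A reported mean feature count of ≈ 332 at a mean
  neighbor count of 7.4 equals 45 × 7.4, implying the quoted "neighbors"
  already describe the channel set used. `includeCenter = TRUE` is the
  default; the flag reproduces either reading.
- **Window alignment.** Results are often reported in coarser bins than
  the window length; the alignment of the 150 ms window to an evaluated
  time point is not stated. The default is *centered* (symmetric ±75 ms),
  with `trailing`/`leading` available. Centers whose window would leave
  the epoch are *undefined* (`NA`), never silently truncated.

The neighbor relation is strict Euclidean distance below a threshold. For
the simulated grids the default threshold is 1.2 × spacing, which gives
the 4-connected neighborhood (diagonals sit at √2 × spacing ≈ 1.41). On
a real 275-channel helmet the threshold would be chosen to land near the
published 4–10 neighbor range.

## Decoding

**Classifier.** Gaussian naive Bayes: per class a prior (training
frequency) and per-feature mean and maximum-likelihood variance; the
decision is the argmax of log prior plus summed log univariate normal
densities, with ties broken toward the first class in the canonical
(factor level) order. Variances are floored at
$\varepsilon = 10^{-9} \times \overline{\mathrm{var}}$ (mean over
class-feature variances; absolute fallback $10^{-12}$) so constant
features cannot produce degenerate densities — the reference toolbox's
exact floor is unstated, so this one is documented and fixed. The
exported `fitGnb()`/`predictGnb()` are the reference implementation; the
searchlight loop runs an algebraically identical compiled path
(RcppArmadillo), and the test suite asserts equivalence of both against a
brute-force density oracle at 1e-10 relative tolerance.

**Cross-validation.** Repeated stratified 5-fold cross-validation,
repeated 5 times with fresh fold assignments, accuracy averaged over all
folds and repeats. Class imbalance is handled by random undersampling to
the minority count. The source description applies undersampling to
"training and test data"; the placement relative to the fold split is
ambiguous, so undersampling is applied *once per repeat, before the
split* — every fold, training and validation alike, is then balanced —
and the convention is switchable (`cvScheme(undersample = )`).

**Reproducible randomization.** Undersampling and fold assignment inside
the searchlight engine are drawn from a deterministic stream seeded per
(scheme seed, channel, time, labeling, repeat), implemented with an
explicit SplitMix64 generator in the compiled code so results are
bit-identical across platforms without storing per-cell RNG state. This
also makes fold noise independent across neighboring cells, which
matters for cluster inference: shared fold assignments would correlate
the cell noise and produce spatially coherent false-positive patches.
Trials with missing samples inside a given searchlight are dropped for
that cell before undersampling.

## Stratified nulls and Z-standardization

Chance level is estimated empirically per subject and cell: the decoding
is repeated for `nRand = 100` label randomizations, and
$Z = (\text{acc} - \mu_{\text{null}})/\sigma_{\text{null}}$. The
randomizations are *constrained*: labels are permuted only within strata
(`constrainedShuffle()`), leaving the per-stratum label composition
exactly intact. Shuffling word-length labels within each object category
makes the null inherit whatever length decodability rides on category
structure; shuffling category labels within joint visual-feature bins
(contrast × edge density × colorfulness, median-split) absorbs low-level
visual confounds. Joint binning is the default where several features
are named; per-feature stratification is available by listing a single
column. Cells with zero null SD are flagged undefined rather than given
infinite Z.

In the demo pipeline configuration the two phonological variables are
additionally stratified *by each other* (length within category ×
density class, density within category × length class). Word length and
neighborhood density are correlated across items by design (r ≈ −0.67),
so each is genuinely decodable at the other's effect site; a null
stratified by category alone leaves that leakage in the observed-minus-
null contrast, and recovered clusters then blend the two sites. This is
a property of the variables, not of the implementation, and the
stratification machinery is exactly the tool that isolates each
variable's own contribution.

## Group-level cluster inference

Subject Z maps are tested against 0 with a one-sample T per cell;
cells exceeding the one-sided critical t at `alphaCluster = 0.05`
(df = subjects − 1) form candidate clusters under spatial adjacency (the
same sensor neighbor graph as the searchlight) plus temporal adjacency
(consecutive evaluated time points). Cluster mass is the sum of T. The
family-wise null is the distribution of the *maximum* cluster mass under
random sign flips of whole-subject maps — the standard exact scheme for
a one-sample test, chosen because the source states the test family but
not the flip scheme — with the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})$, so p
is never exactly zero. Inference is one-sided (above-chance only), and
only Z maps are tested, never raw accuracies. The test suite checks the
Monte-Carlo p against exhaustive $2^8$ enumeration for 8 subjects and the
family-wise type-I rate against its binomial band on null simulations.

## The synthetic-data generator

The generator emulates the structure of a picture-naming MEG study:

- **Stimulus table** (`makeStimulusTable()`): items balanced over four
  object categories; syllable counts 1–3 with mostly mono-/bisyllabic
  words; neighborhood density as a negative-binomial count (mean ≈ 12,
  SD ≈ 10); SUBTLEX-style frequency per million as a lognormal
  (median ≈ 5, mean ≈ 8). The three lexical marginals are coupled through
  a Gaussian copula whose latent correlations are calibrated on a large
  latent sample (4000 draws, 3 fixed-point passes) against the
  attenuation the discrete marginals introduce, so the realized item
  correlations approach the canonical targets (−0.67, −0.37, +0.32).
  Frequency enters correlation checks on the log scale, as skewed
  per-million counts conventionally do. Visual features are sampled
  independently of the lexical variables. Derived labels: length class
  (short = monosyllabic), four density quantile classes (ties to the
  lower class, so the binning is a pure function; explicit published
  count boundaries are available via `discretizeBreaks()`), and low/high
  median splits of the visual features.
- **Epochs** (`simulateEpochs()`): per subject, white Gaussian channel
  noise plus, per effect, a per-class amplitude times a smooth envelope
  on the effect's channels and window; −100 to 1000 ms at 300 Hz by
  default. A configurable fraction of trials (default 17%, matching 3%
  naming errors + 14% disfluencies excluded in the emulated study) is
  flagged invalid; artifact masks black out ~60 ms segments on a small
  fraction of trial × channel pairs (default 0.5%), stored as `NA` plus
  mask. Per-subject seed streams make any subject reproducible in
  isolation.
- **Waveforms.** Two envelope identifiers exist. `halfcosine` is a
  flat-top window with 10 ms half-cosine ramps — a sustained field
  offset, convenient for mean-difference oracles. The demo effects use
  `burst`: the same envelope times a 10 Hz carrier, zero-mean over a
  100 ms window. The distinction matters: a sustained offset has strong
  DC content *within its window*, and a zero-phase 1 Hz highpass smears
  that energy far outside the window, making the effect decodable across
  much of the epoch — physically, real evoked components are oscillatory
  transients with little sub-band energy, and `burst` models that. The
  flat-top's 10 ms ramps only bound the *upper* spectral edge.
- **Demo effect sizes.** The three demo effects (category 150–250 ms,
  length 250–350 ms, density 350–450 ms, in disjoint grid regions) use
  moderate amplitudes (0.4–1.2 in noise-SD units after the planar
  transform's geometry) chosen once so that in-window decoding
  accuracies sit tens of percentage points above chance at most —
  recoverable at desk scale with 8–12 subjects, yet far from ceiling and
  with off-window cells at chance. Published sensor-level naming studies
  report raw accuracies only a few points above chance; the demo is
  deliberately stronger than that, because its purpose is a reliable
  end-to-end recovery check, not effect-size realism.

What the generator does *not* emulate: forward-model field spread
(dipoles, head geometry), colored/oscillatory background noise, cardiac
and ocular artifact waveforms (masks stand in), head movement, or real
stimulus images. Passing recovery tests therefore demonstrates the
statistical machinery — calibration of nulls, family-wise error control,
latency and topography recovery under the modeled conditions — not
performance on any particular real recording.

## Recovery metrics

`runPipeline()` compares significant clusters (p < 0.05) against the
injected ground truth. Each effect is matched to the significant cluster
of its variable with the highest channel-set Jaccard overlap (correlated
variables can produce additional genuine clusters at each other's
sites). The recovered onset is the earliest time at which the matched
cluster holds at least 25% of its peak per-time cell count (minimum 2):
cluster extent at the forming threshold is noisy at its fringes, and a
one- or two-cell excursion should not define when an effect begins. With
a centered 150 ms window, a cell one 50 ms step before the injected
onset legitimately overlaps the effect, so onset errors of −50 ms are
expected and accepted.

## Problem sizes used by the tests

The packaged checks run at desk scale, chosen to finish a full suite in
well under half an hour on one core: an 8 × 8 sensor grid (4-connected),
60 items × 3 repetitions, 12 subjects and 100 randomizations for null
calibration (two evaluated time points), 8 subjects and 30
randomizations at 12 time points for the three-effect recovery run,
500–2000 group permutations, and 200 null simulations for the type-I
check. Null-calibration and specificity runs skip the bandpass stage
(the simulated noise is already in-band white; filtering is exercised by
its own oracle tests), while the recovery run executes the full
pipeline including filtering.

## Known limitations

- The planar-gradient estimate is a local finite-difference scheme on a
  flattened layout; it does not model sensor orientation or curvature.
- Undersampling discards data; with strongly imbalanced classes the
  effective trial count per fold can get small, and cells whose smallest
  class drops below the fold count are flagged undefined rather than
  decoded.
- Cluster-based inference licenses statements about the *existence* of
  an effect within a cluster, not sharp claims about its exact boundary;
  the recovery metrics inherit that softness, which is why onsets use
  the robust rule above.
- The empirical null costs `nRand` full decodings per cell; the compiled
  engine makes this tractable, but wall-time still scales linearly in
  channels × time points × randomizations.
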
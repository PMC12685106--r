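---
title: "Methods and design notes for the desimsi pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the desimsi pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desimsi)
```

This vignette documents the statistical procedures the package implements,
the parameters that matter and why their defaults are what they are, what
the synthetic cohort generator does and does not emulate, and the design
choices made where the methodology was genuinely open.

## The analysis chain

The unit of analysis is one averaged spectrum per patient per tissue class.
Pixel-level spectra inside the annotated region of interest are pooled,
matched into features, and averaged (`average_roi()`); the per-patient
averages are then matched across patients within the analysis window
(`match_peaks()`), normalized (`pqn_normalize()`), and passed to
classification, univariate statistics, and annotation. Working at patient
level keeps the cross-validation honest — all of a patient's pixels stand
or fall together — at the cost of discarding spatial heterogeneity within
a section.

### Peak matching

Mass spectrometers drift at the parts-per-million level, so the "same" lipid
peak appears at slightly different m/z in every spectrum. Peaks pooled from
all spectra are sorted and chained left to right: the chain closes when the
gap from the last member to the next peak exceeds `max_shift_ppm`
(default 8 ppm) converted to daltons at the running intensity-weighted
consensus. A refinement pass then enforces two contracts: each spectrum
contributes at most one peak per feature (nearest in ppm wins; ties go to
the higher-intensity peak), and every member lies within `max_shift_ppm` of
its feature's final consensus — peaks violating either are split off and
re-clustered until the assignment is stable. The procedure is deterministic
and invariant to the order of the input spectra. Single-linkage chaining
(adjacent-gap closure) rather than consensus-gap closure was chosen because
a cluster's low tail otherwise drags the running consensus away from later
members and shears off spurious singleton features; with chaining, a cohort
planted with 207 true features yields exactly 207 consensus features.

### Probabilistic quotient normalization

Ionization efficiency varies per acquisition, multiplying whole spectra by
nuisance factors. PQN estimates each sample's factor as a robust summary of
its feature-wise intensity quotients against the element-wise mean spectrum
of all samples; the sample is then divided by that factor. The default
summary is the median quotient (standard PQN); the mean quotient is a
switch (`quotient = "mean"`) because "PQN-mean" in the field ambiguously
denotes the mean *reference*, the mean *quotient*, or both — we read it as
the mean reference with median quotient, the variant that is robust to the
minority of genuinely differential features. Quotients are computed only
over features with a positive reference (a zero reference leaves the
quotient undefined), and an all-zero sample is an error, not a silent NaN.
Exact multiplicative differences between samples are removed exactly;
re-normalizing an already normalized matrix returns factors of 1 — exactly
for samples that differ only by scale, and within a few percent otherwise,
since the median quotient of noisy normalized data re-concentrates at 1
only as the feature count grows.

### RMMC-LDA classification

With `p` features and `n` patients, classical LDA needs `S_w^{-1}`, which
does not exist when `p > n`. The maximum margin criterion replaces the
Rayleigh quotient with the difference criterion `w'(S_b - S_w)w`, solvable
as a plain symmetric eigenproblem of `(S_b - S_w)` (symmetrized before
decomposition to suppress floating-point asymmetry). Recursion extracts
further components by deflating the data and re-solving restricted to the
orthogonal complement of the components already found — the restriction
matters, because a deflated component has eigenvalue exactly 0 and would
otherwise be re-selected once the remaining spectrum turns negative.
Default `k = 1` for two-class problems; the class call is the nearest class
mean in score space, with ties broken toward the first class level.

Two design points deserve emphasis:

* **No unit-variance standardization by default.** Standardizing gives all
  features equal scatter weight; with ~200 uninformative features and only
  ~60 patients the leading eigenvector then partially fits sampling noise,
  and the nearest-class-mean threshold miscalibrates against held-out
  patients of the smaller class. On the raw intensity scale the scatter is
  concentrated in high-intensity lipid features — which in this application
  are also the discriminatory ones — and leave-one-patient-out performance
  is markedly better and stable. `standardize = TRUE` remains available for
  data where intensity and information are not aligned.
* **Leave-one-patient-out.** Every row of a held-out patient is excluded
  from the fold's fit; a per-fold audit (`folds$leaked`) asserts this by
  construction. A class vanishing from a training fold is an error naming
  the patient rather than a silently degenerate fit. Inside a fold a
  training class reduced to a single patient is accepted (it contributes
  zero within-class scatter); a top-level fit still requires two samples
  per class.

### Univariate statistics

Per-feature one-way ANOVA (equal-variance; for two groups this is the
squared pooled t) on normalized intensities without log transform —
log10 is used for display only. Multiple testing is controlled by
Benjamini–Hochberg; fold change is the ratio of group means, so a feature
elevated in the first group reports a value above 1, and a zero denominator
yields a flagged `NA` rather than an error. Demographic 2×2 tables use
Fisher's exact test with the point-probability two-sided rule (the sum of
all tables, with margins fixed, no more probable than the observed one) —
the rule that reproduces standard printed cohort-table p-values — and the
age-type continuous comparison uses Welch's t by default with the pooled
variant switchable.

### Annotation

Accurate-mass lookup against a bundled reference of deprotonated
glycerophospholipids, extensible via TSV. The ppm error convention is
`(observed - theoretical)/theoretical * 1e6`, signed; hits are ranked by
absolute error with ties broken by lower isotopologue offset and then name.
¹³C isotopologues are matched at `k * 1.0033548` Da above the monoisotopic
mass (`max_isotope = 1` by default). The default tolerance of 10 ppm covers
the largest error among the reference's published identifications
(9.88 ppm); the bundled table stores printed theoretical masses rather than
masses computed from molecular formulas, and MS/MS strings are opaque
metadata passed through unmodified, never interpreted.

### Protein statistics and integration

Each protein is related to tissue status by a univariate logistic
regression (IRLS, tolerance 1e-8, 100 iterations); odds ratios are per
expression unit (per SD switchable), intervals are Wald `exp(beta ± 1.96
se)` — the interval type was an open choice; Wald matches the
report-OR-with-CI convention. Complete or quasi-complete separation is
detected (fitted link beyond ±15, exploding standard errors, or
non-convergence) and flagged with an infinite-OR marker; flagged fits are
excluded from the FDR denominator and counted, because at small n the Wald
p-value of a separated fit is meaningless (the Hauck–Donner effect makes it
large, not small). For integration, lipids are normalized per patient by
total intensity and proteins per antibody by maximum — "per antibody" keeps
every protein on [0, 1] and was chosen over per-patient maxima, which would
couple unrelated antibodies. Association between species is cosine
similarity across the shared patients, computed for every lipid-lipid,
protein-protein and lipid-protein pair; a classical two-block canonical
correlation analysis is deliberately not implemented, since the heatmap and
dendrograms the analysis produces are functions of the pairwise cosine
matrix alone. Clustering uses average linkage by default (centroid and
complete offered); average and complete linkage guarantee monotone merge
heights, centroid does not.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the pipeline
assumes, not mass spectra per se:

* two patient classes (default 50 cancer / 14 benign) on a pixel grid
  (default 20×20) with a circular tissue region and near-zero (1%)
  off-tissue intensity;
* seven planted discriminatory features at published lipid m/z values with
  cancer/benign fold changes 1.23–1.28 and base intensity 100 a.u.;
* 200 background features at uniform-random m/z, at least 50 ppm from every
  other feature, with log-uniform base intensities (20–200 a.u.);
* per-pixel log-normal intensity noise (CV 0.3), a per-pixel uniform
  total-ion-current factor (0.5–2.0) exercising PQN, and per-peak Gaussian
  m/z jitter (SD 2 ppm) exercising the matcher. The jitter is truncated at
  3.5 SD so that the within-feature spread stays below the 8-ppm matching
  window: at ~5 million pixel-peak draws, untruncated 4-sigma tails would
  manufacture hundreds of spurious singleton features that no real matching
  tolerance is meant to absorb;
* a per-patient, per-feature multiplicative log-normal effect
  (`patient_cv`, default 0.1). This field is the generator's one addition
  beyond the per-pixel law: averaging ~200 tissue pixels shrinks pixel
  noise by a factor of ~14, so without between-patient biological
  variability every classifier would be trivially perfect and
  cross-validation would test nothing. A 10% between-patient CV makes
  patient-level effect sizes finite (log(1.24)/0.10 ≈ 2.2 per feature)
  while leaving the planted effects recoverable — the regime the analysis
  is designed for;
* optional phenotype-linked features (high- vs low-risk metabolic
  phenotype within one diagnostic class). The contrast is mean-preserving:
  high-risk patients are scaled by `f/(p·f + 1 − p)` and low-risk by
  `1/(p·f + 1 − p)`, so the high/low intensity ratio equals `f` while the
  class mean — and therefore the cancer-vs-benign fold change of a feature
  that is also class-planted — is unchanged. This is the only way a single
  multiplicative model can satisfy published class-level and
  within-class-phenotype fold changes at the same m/z simultaneously;
* a protein panel (default 282 antibodies, 104 differential at 1.5 SD,
  baseline 1 ± 0.2 a.u.) with an optional subset generated correlated
  (default 0.9, within class) with the patient-level latents of planted
  lipids, to exercise the integration stage.

The RNG stream is consumed in one documented order (background features,
metadata, patient latents, then per-patient pixel draws), so a
configuration is its cohort. What the generator does **not** emulate:
profile-mode (non-centroided) peaks, isotope envelopes beyond explicit ¹³C
features, chemical noise baselines, spatial autocorrelation within tissue,
batch or acquisition-day effects, and missingness structure. Passing tests
on synthetic cohorts therefore demonstrates the pipeline's correctness
under its stated model — recovery of known planted effects with calibrated
false-positive behaviour — not its performance on any real instrument's
output.

## Numerical choices and degenerate inputs

* Eigendecompositions operate on symmetrized matrices; projection columns
  are unit-norm, mutually orthogonal within 1e-8, and sign-fixed (largest
  loading positive) for determinism.
* ANOVA conventions: all-equal data → F = 0, p = 1; zero within-group
  variance with differing means → p = 0. Welch t: two identical constant
  groups → t = 0, p = 1.
* Fold change with a zero denominator is `NA`, flagged, never an exception;
  Fisher tables with a zero margin are errors.
* imzML stores m/z as 64-bit and intensity as 32-bit little-endian floats
  (common practice; preserves ppm-level mass precision), with a shared UUID
  in XML and binary and 1-based pixel positions on disk converted to the
  package's 0-based convention in memory. Readers reject missing
  companions, UUID mismatches and non-ascending m/z axes by name.
* The pipeline's stages communicate only through written artifacts
  (TSV/JSON), so any stage can be re-run from its predecessors' files;
  a failed stage leaves partial results and a manifest naming the failure.

## Problem sizes used by the tests

The test suite runs cohorts between 10 and 64 patients with 6×6 to 20×20
pixel grids and 10–200 background features; generator-convergence checks
use 240–300 patients on small grids. These sizes keep the full suite under
half a minute while leaving every statistical check comfortably powered;
the acceptance script runs the full default 50/14 cohort at 20×20.

## Known limitations

* Two-class designs only; multi-class molecular subtyping is out of scope.
* The classifier reports calls and scores, not calibrated probabilities.
* Annotation is identity lookup; it cannot distinguish isomers sharing a
  sum composition (the MS/MS notes carry that information as free text).
* The nearest-class-mean rule assumes comparable class covariance in score
  space; with severe imbalance and weak signal the threshold inherits the
  small class's estimation noise.
* Logistic odds ratios are per expression unit unless `per_sd = TRUE`;
  comparisons across proteins on different scales should use the latter.
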
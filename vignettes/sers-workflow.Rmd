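---
title: "Methods: the serum SERS diagnostic workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the serum SERS diagnostic workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sersdx)
```

This vignette documents the models, parameter choices and numerical
decisions behind `sersdx`, in the spirit of a methods section: what each
stage assumes, which knobs matter, and what the synthetic validation does
and does not demonstrate about real serum spectra.

## The measurement model

A serum SERS acquisition is modelled as

$$ y(\nu) \;=\; b(\nu) \;+\; \sum_k A_k \, \phi(\nu - \nu_k) \;+\;
   \varepsilon(\nu), $$

where $\nu$ is the Raman shift on a fixed 200–1800 cm⁻¹ grid at 2 cm⁻¹
(801 points), $b$ is a smooth autofluorescence background, $\phi$ a
band profile, $A_k \ge 0$ band amplitudes and $\varepsilon$ instrument
noise. Diagnosis rests on group differences in a subset of the $A_k$:
relative to normal serum, each tumour class increases some bands and
decreases others (the catalogue's effect lists; e.g. hypoxanthine at
723–727 cm⁻¹ increases in all three tumour groups).

## Synthetic cohorts

`synthetic_config()` defaults encode the study conditions the workflow is
designed for:

* cohort design 20 PA / 21 WT / 19 MEC / 31 Normal patients; 4–6 spectra
  per patient, drawn uniformly and then nudged (within 4–6) so the group
  totals are 101/105/95/153 — 454 spectra in all;
* bands at the 16 catalogue positions plus the unassigned 450 cm⁻¹ site,
  pseudo-Voigt (half Gaussian, half Lorentzian) with 12 cm⁻¹ FWHM —
  published spectra show band shapes but do not parameterize them, so a
  generic profile and width were fixed once;
* base amplitudes of order 0.4–1.5 a.u. with hypoxanthine dominant;
* group effects: each listed "increased" band is multiplied by
  `effect_size` (default 1.5) and each "decreased" band divided by it —
  symmetric on the log scale;
* a random degree-4 polynomial background (`baseline_amplitude = 5`,
  several times the band scale, as serum autofluorescence is), with a
  degree-5 option to probe model mismatch in the baseline corrector;
* i.i.d. Gaussian noise, `noise_sd = 0.05` a.u.

Two structural choices deserve explanation.

**Per-band patient effects.** The patient random effect is a *vector* of
independent log-normal multipliers, one per band (`patient_sd = 0.3` on
the log scale), shared by all spectra of the patient; per-spectrum
jitter (`spectrum_sd = 0.05`) is likewise per band. A single scalar
multiplier per patient would be mathematically removed by area or vector
normalization, leaving leave-one-patient-out no harder than
leave-one-spectrum-out; a per-band signature survives normalization and
reproduces the phenomenon the two cross-validation schemes are meant to
expose — per-spectrum evaluation can recognize the *patient*, not the
disease.

**The common serum envelope.** Twenty broad (35 cm⁻¹ FWHM),
group-invariant bands at positions away from all catalogue bands carry no
diagnostic signal but most of the spectral mass. Without them, a group
with many increased bands (WT increases 12 of 17) merely rescales under
area normalization, and its generated "increases" vanish or flip sign in
the difference spectrum; with a stable shared area, multiplicative band
changes survive normalization with their signs intact, as in dense real
serum spectra.

What the simulator does **not** emulate: spectral congestion beyond the
envelope, wavenumber miscalibration and instrument drift, cosmic-ray
spikes, detector nonlinearity, heteroscedastic shot noise, and any
covariance between bands induced by shared metabolism. Passing tests
therefore demonstrate the *pipeline's* correctness and its statistical
behaviour under a plausible generative model — not clinical performance
on real serum.

## Preprocessing

Stage order is fixed: quality control → baseline removal → smoothing →
normalization.

* **QC** rejects spectra with non-finite values or a run of at least 25
  consecutive points at ≥ 99.9 % of the cohort-wide maximum intensity
  (flat-topped runs are the signature of detector saturation; smooth
  natural maxima do not stay within 0.1 % of the global maximum for
  50 cm⁻¹).
* **Baseline removal** is iterative modified polynomial fitting
  (Lieber-style peak clipping): fit a degree-4 polynomial, replace points
  above the fit by the fit, refit; stop when the fit changes by less than
  `baseline_tol = 1e-6` of the spectrum maximum or after 100 iterations.
  A single unweighted polyfit is biased upward by the peaks; clipping
  removes that bias at the cost of a small downward ringing (sub-percent
  of the background) far from peaks, and recovers band apexes to within a
  few percent — both bounds are asserted in the test suite. The corrected
  spectrum is floored at zero.
* **Smoothing** is Savitzky–Golay, window 11 points, order 3 (neither is
  given by typical acquisition-software defaults, so both are exposed);
  the implementation preserves any polynomial up to the fit order,
  including at the edges.
* **Normalization** defaults to unit trapezoidal area over 200–1800 cm⁻¹;
  vector (unit Euclidean norm) and min–max modes are provided because the
  original normalization method in this family of studies is typically
  unrecoverable — the default is a documented reproduction assumption,
  not a claim.

## Difference-spectrum analysis

Group mean spectra carry pointwise means, sample SDs (presentation bands,
as in the usual mean-±-SD figures) and the patient count. The difference
of two means carries a conservative pointwise standard error,

$$ \mathrm{se}(\nu) = \sqrt{ s_A^2(\nu)/P_A + s_B^2(\nu)/P_B }, $$

with $P$ the *patient* counts: spectra of one patient are correlated, so
the patient count, not the spectrum count, is the effective sample size.

Signed peaks are strict local maxima of the difference (increases) and of
its negation (decreases). The default acceptance rule keeps a maximum
when its apex height is at least **6 × se** at that position. Two simpler
rules were evaluated and rejected during development: a threshold on the
roughness of the difference (MAD of second differences) is blind to the
band-shaped bumps that patient sampling noise produces in a smoothed
mean; and thresholding topographic prominence against the local se leaks
false positives in flat inter-band regions, where prominence references a
distant saddle. The 6-se apex rule separates the two regimes cleanly: on
effect-free cohorts the maximum observed apex-to-se ratio stays below
~5, while generated effect bands on low-variability cohorts sit at ratios
of 9 and above. The multiplier is deliberately conservative — with 30 %
per-band patient variability and ~10 patients per group a 1.5× band
change is *not* significant by this rule, which is the statistically
honest answer. An explicit `min_prominence` bypasses the rule with a
global prominence threshold; `min_separation` (default 10 cm⁻¹) thins
same-signed hits, strongest first.

Assignment widens each catalogue range by `tolerance = 3` cm⁻¹ and picks
the nearest entry on overlap; every hit receives exactly one label or
`"unassigned"`. Generated band centres are range midpoints snapped to the
grid, so a listed position can sit up to ~5 cm⁻¹ from its generated site;
tests therefore match hits within 6 cm⁻¹.

## Classification

Each binary task uses the full 801-point normalized spectra as features.
The SVM is RBF-kernel C-classification (libsvm via `e1071`), with
features column-standardized inside the fit (after area normalization the
absolute scale is ~10⁻³, and standardization puts squared distances in
the range the conventional powers-of-two gamma grid covers).
Hyperparameters are selected by jackknife: exhaustive grid search over
`C ∈ 2^{-5..15}`, `γ ∈ 2^{-15..3}` (stride 2) scored by leave-one-out
accuracy on the training data, computed via libsvm's internal n-fold
cross-validation (with k = n the folds are singletons, so the result is
deterministic). Ties break toward the smallest C, then the smallest γ —
the least complex model among equals.

Cross-validation schemes: LOSO holds out one spectrum per fold; LOPO
holds out all spectra of one patient, with train/test patient
disjointness asserted in every fold. By default hyperparameters are
re-optimized within each fold (`optimize = "nested"`), avoiding selection
leakage; `optimize = "once"` selects them once on the full task, the
cheaper and historically common protocol, and is what the bundled
acceptance script uses. A LOPO fold whose training half loses an entire
class is skipped and reported rather than silently predicted.

The two-step report evaluates Normal vs {PA, WT, MEC} (step 1) and
PA vs WT, PA vs MEC, WT vs MEC (step 2). Positive-class conventions
follow the published tables this layout mirrors: normal serum is the
positive class in step-1 per-spectrum tables, the tumour in step-1
per-patient tables, and the first-named group in step 2; the report
stores the convention per row. Display rounding is half-away-from-zero
(percentages to 1 decimal, MCC to 3), matching the apparent convention
of such tables; stored values keep full precision.

## Statistical validation design

The acceptance suite asserts, among others:

* **Published-table arithmetic.** Reconstructing confusion counts from
  each table's printed SP/SE and the group sizes reproduces the printed
  ACC cells exactly at printed precision and the per-spectrum correct
  counts; LOSO MCC cells reproduce to 3 decimals. Two kinds of
  documented inconsistency are tolerated: one ACC cell disagrees with its
  own implied counts and is excluded, and the per-patient MCC cells
  deviate from their implied counts by up to ~0.013, so they are checked
  within 0.015. One column's SP/SE only round-trip with the class roles
  swapped; rates are therefore checked within half-count granularity
  (0.55 points).
* **Null cohorts.** With `effect_size = 1` and `patient_sd = 0` all
  groups are generated identically; the six LOSO accuracies must lie in
  a family-wise 95 % binomial band around 0.5 (Bonferroni across the 12
  checks), and LOPO accuracies must not rise above it. Two deliberate
  asymmetries: the null uses `patient_sd = 0` because with patient
  structure a null cohort is only exchangeable at the *patient* level —
  LOSO then measures identity leakage (accuracy near 1.0), which is real
  behaviour, not a bug; and LOPO is allowed below the band because under
  pure label noise the fitted machine degenerates to majority voting,
  and removing a whole patient tilts the training majority against the
  held-out class — a known small-sample cross-validation artifact.
* **Effect recovery.** A 1.5× effect with mild patient variability (0.1)
  yields LOSO accuracy above 0.8 on the malignant-vs-normal task, and
  with strong patient variability (0.6) LOSO ≥ LOPO in at least 8 of 10
  seeded replicates.
* **Band recovery.** On low-variability cohorts the difference-spectrum
  hits contain every generated effect band of every tumour group, with
  the correct signs, and effect-free cohorts yield no hits at default
  thresholds.

Problem sizes in the tests and the acceptance script are scaled-down
study designs (4–8 patients per group with 3–4 spectra in tests; a
10/10/10/15-patient cohort with the 4–6 draw in the acceptance script)
and reduced hyperparameter grids (C ∈ 2^{0,4,8}, γ ∈ 2^{-12..-6}); these
sizes are the package's choice of validation scale and are stated here so
they can be revisited.

## Known limitations

* The baseline corrector assumes a background no rougher than its
  polynomial degree; sharper fluorescence structure leaks into the
  corrected spectrum (the degree-5 generator option exists to study
  this).
* The apex-significance detector treats bands independently; strongly
  overlapping bands (closer than ~the FWHM) shadow each other's shoulders
  and are reported as single hits.
* Area normalization makes band changes relative: a uniform up-regulation
  of all bands is undetectable by construction, and large asymmetric
  effects slightly depress unaffected bands in the difference spectrum
  (visible as small spurious opposite-signed hits).
* LOSO results on repeated-measures cohorts should be read as an upper
  bound; LOPO is the clinically meaningful estimate, and with 4–6 spectra
  per patient it is noisy.
* MCC is reported with the 0-on-degenerate-marginal convention; tasks
  with skipped LOPO folds no longer satisfy `tp+fn = n_pos` for the
  skipped patients, and the report records the skip count.
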
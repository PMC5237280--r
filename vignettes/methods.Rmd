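---
title: "Methods: spectral pattern recognition for single-voxel brain MRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral pattern recognition for single-voxel brain MRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mrspattern` implements a supervised pattern-recognition workflow for
in-vivo single-voxel ^1^H-MR spectra of rat brain: normalize each spectrum
to the contralateral hemisphere, select a handful of discriminative
spectral datapoints, fit a three-class Fisher discriminant, and judge the
model on an independent, chronologically later test set. This vignette
records the model, the tunable parameters, and the design decisions taken
where the workflow leaves room for interpretation.

## Data model and normalization

A spectrum is a vector of real-part intensities on a fixed chemical-shift
axis from 4.5 down to 0 ppm (1383 datapoints by default, so one datapoint
every 4.5/1382 ≈ 0.0033 ppm). All indices are 1-based, with index 1 at
4.5 ppm.

Peak heights are made comparable across animals by unit-length
normalization to the contralateral area (UL₂CA): every datapoint is
divided by the Euclidean norm of the same animal's non-infarcted
(contralateral) spectrum over the whole stored window and multiplied by
100. Two properties anchor the implementation and are asserted by tests:
a reference spectrum normalized to itself has norm exactly 100, and the
transform is invariant to any joint rescaling of spectrum and reference,
so scanner gain drops out. The summation window is the full stored vector;
reference pairing maps each lesion-side spectrum to the same session's
contralateral spectrum, healthy hemispheres to the homologous opposite
hemisphere, and a spectrum that *is* the designated reference to itself.
Whether healthy hemispheres should instead self-normalize is not
determined by the workflow's description; both pairings can be expressed
through the cohort's contralateral map.

Chemical-shift referencing aligns the total-creatine (TCr) maximum with
the datapoint nearest 3.03 ppm, searching ±0.15 ppm and shifting by whole
datapoints only, so intensity values are never interpolated. A spectrum
without a local maximum in the window (e.g. flat) is returned unshifted
with a warning.

## Feature selection

Candidate features are individual datapoint heights. Selection is greedy
forward search under the correlation-based feature subset (CFS) merit

$$M_S = \frac{k\,\bar r_{cf}}{\sqrt{k + k(k-1)\,\bar r_{ff}}},$$

with $k$ the subset size, $\bar r_{cf}$ the mean feature–class
correlation and $\bar r_{ff}$ the mean pairwise feature–feature
correlation. Ties in merit break toward the lower datapoint index (higher
ppm), making the trace deterministic. A floating variant (conditional
exclusion after each inclusion) is available behind a flag but off by
default.

Two correlation measures are implemented:

* **Symmetric uncertainty (default).** Features are discretized against
  the class labels by the Fayyad–Irani MDL criterion; relevance and
  redundancy are the symmetric uncertainty
  $SU(X,Y) = 2\,I(X;Y)/(H(X)+H(Y))$ between the discretized variables.
  Datapoints carrying no class information collapse to a single bin and
  get $SU = 0$, so baseline and noise regions are effectively excluded.
* **Pearson (option).** Relevance is the mean over the three one-vs-rest
  indicators of the absolute point-biserial correlation; redundancy is
  absolute Pearson correlation.

The SU formulation is the default because of how the two measures rank the
canonical biomarkers on calibrated cohorts. The 1.33 ppm resonance
separates *all three* tissue states (its published class medians are far
apart with barely overlapping IQRs), while TCr separates only
non-infarcted tissue from the rest. A one-vs-rest Pearson mean dilutes a
tri-modal feature — its middle class has a near-zero indicator
correlation — and therefore structurally ranks TCr above 1.33 ppm, whereas
mutual information rewards full three-way separation. Only the SU default
reproduces the qualitative behaviour expected of this workflow, where
1.33 ppm leads the selection for infarct evolution.

Two properties of CFS deserve explicit mention because they shape the
selected sets. First, the merit of a subset containing a perfect duplicate
of a strong feature equals (for $k=1$, and approximately for larger $k$)
the merit of the original subset, while adding a genuinely complementary
but weaker feature can *lower* the mean relevance faster than the
redundancy denominator grows. A forced-size forward search may therefore
admit a second datapoint from the same resonance before a weaker distinct
resonance — which is also visible in the real workflow this package
models, where a brain-regions classifier selected the two adjacent
datapoints 3.04 and 3.05 ppm of the same TCr resonance. Second, the folk
invariant "adding an exact duplicate never increases merit" is false in
general: with $S = \{f, g\}$, $r_f \gg r_g$ and $corr(f,g) \approx 0$,
duplicating $f$ raises the mean relevance enough to beat the added
redundancy. The tests assert the singleton equality case, which does hold
exactly.

The recommended model-size cap is a third of the smallest class (never
below 2); the sweep may deliberately exceed it, as the original workflow
does, and then warns.

## Fisher discriminant and classification

On the selected columns the classifier solves the generalized eigenproblem
of the between-class scatter against the pooled within-class scatter and
keeps the two leading eigenvectors (classes − 1 dimensions). Numerical
choices:

* **Regularization.** If the within-class scatter has condition number
  above 10^10^ (as happens when features approach cases per class, and
  routinely inside bootstrap replicates), a ridge of
  $10^{-6}\,\mathrm{tr}(S_w)/p$ is added to its diagonal and recorded in
  the fitted model.
* **Determinism.** Eigenvector signs follow a fixed convention (largest
  loading positive), so refits are bit-identical.
* **Decision rule.** Nearest class centroid in the latent space by
  Euclidean distance, with equal priors; exact ties go to the first class
  in declared order. Whether the original software weighted latent
  dimensions by eigenvalue is unknown; unweighted Euclidean distance is
  the simplest rule consistent with a 2-D latent-space plot.

## Evaluation

The balanced error rate averages the per-class misclassification
proportions (×100), so each class counts equally regardless of size. The
training-set accuracy (CCC, percent correctly classified) is estimated by
bootstrap: cases are resampled with replacement, the discriminant is refit
on the fixed feature set, and each replicate is scored *on the full
original training set*; replicates that lose a class (or leave it with a
single case, which would make the scatter undefined) are redrawn and
counted. Out-of-bag scoring would estimate generalization instead of
training accuracy and is intentionally not the default.

The feature-count sweep refits the model for every size $k$ in range,
records bootstrap CCC (training) and BER (independent test set), and picks
the **first local minimum** of test BER: once the test error starts
rising, larger models are treated as overtraining even if a later size
dips slightly lower. A global-minimum mode exists behind a flag.

One-vs-rest diagnostics (sensitivity, specificity, PPV, NPV) come from
dichotomized confusion counts, with zero-denominator metrics reported as
`NA` rather than 0. ROC AUCs use the rank (Mann–Whitney) formulation with
midranks for ties and the Hanley–McNeil standard error. The continuous
one-vs-rest score is this package's construction (the underlying workflow
does not state one): distance to the nearest non-target centroid minus
distance to the target centroid in the latent space.

The chronological split emulates prospective accrual: animals are sorted
by the numeric part of their identifier and assigned whole to the training
set until about two thirds of the spectra are covered; everything later is
test. No animal ever straddles the split.

## Univariate follow-up

Selected features are summarized per class as median and 25th–75th
percentile. The percentile convention matters for small classes: linear
interpolation of order statistics (R type 7) is the default, with type 6
(the convention of common commercial statistics software) available,
because reproducing published IQRs can depend on the choice. Distribution
checks use the Lilliefors-corrected Kolmogorov–Smirnov test (per class,
n ≥ 4) and Levene's test (median-centered) across classes; group
differences use Kruskal–Wallis with the tie-corrected H statistic, and
post-hoc pairwise comparisons use Dunn's rank z-tests with Bonferroni
adjustment over the three pairs — the concrete post-hoc procedure is not
specified in the source workflow, so Dunn + Bonferroni was chosen as the
standard rank-based follow-up, implemented directly because no installed
package provides it.

## Synthetic cohorts

The generator emulates *processed* spectra, not acquisition physics: each
spectrum is a sum of Lorentzian/Gaussian resonances (ML –CH₃ 0.85, Lac and
ML –CH₂ co-located at 1.33, NAA 2.02, glutamine/glutamate 2.35, TCr 3.03,
choline 3.21, myoinositol 3.62, TCr –CH₂ 3.93 ppm) plus a smooth random
baseline (spline through 8 random knots, sd 0.4 UL₂CA units) and Gaussian
noise (sd 0.2 units) passed through a 3-point moving average, standing in
for the net effect of line broadening. A per-spectrum global shift jitter
(sd 0.004 ppm ≈ 1.2 datapoints) models residual referencing error; a
per-animal lognormal gain (log-sd 0.3) models scanner scaling and cancels
under UL₂CA.

Class information enters only through the diagnostic resonances of each
scenario; all other peaks have class-invariant amplitude distributions.
Amplitudes are lognormal in shape but **two-piece**: the lower and upper
log-sd are fitted separately to the published 25th and 75th percentiles,
so the median and both quartiles are matched exactly. A single symmetric
log-sd can only match the quartile *ratio*, and the subacute 1.33 ppm
reference distribution (median 19.88, IQR 10.38–22.11) is strongly
asymmetric in log space — a symmetric fit would imply an upper quartile
near 29 and exaggerate the upper tail. Co-located components of one
diagnostic group (Lac + ML at 1.33 ppm, split 50/50, 70/30 and 30/70
across the three infarct-evolution classes) share their random draw so the
distribution of their *sum* is the calibrated one.

Calibration is numerical: a fixed-point loop sets each diagnostic
resonance's apex amplitude so the **noiseless class template** reproduces
the published class median at the diagnostic datapoint (accounting for
tails of neighbouring peaks), while the class-invariant background
amplitudes are jointly rescaled so the noiseless non-infarcted template
has Euclidean norm exactly 100 — the self-consistency condition of UL₂CA
units. The TCr linewidth (0.076 ppm FWHM Lorentzian) is the value at which
one amplitude reproduces the published height ratio between the 3.04 and
3.05 ppm datapoints; other linewidths are plausible in-vivo values
(0.03–0.14 ppm). Where a target must be met at two datapoints of one peak
(TCr in the brain-regions scenario) the amplitude is the least-squares
compromise, which lands within a few percent of both.

Cohort structure mirrors the study design: each "stroke" animal
contributes its lesion-side spectra plus one contralateral non-infarcted
spectrum (which doubles as its normalization reference), remaining
reference-class spectra come from "healthy" animals in homologous pairs,
and the animal roster interleaves groups so the chronological split keeps
the classes approximately balanced. Default cohort sizes are the study's:
48/20/14 spectra (infarct evolution) and 48/82/34 (brain regions).

What the generator does **not** emulate: J-coupling and multiplet
structure, macromolecule baselines with class structure, water residuals,
field-inhomogeneity lineshape distortions, per-peak frequency jitter, and
within-class correlation between metabolite amplitudes (independence is
assumed; real amplitudes co-vary through cell density and pathology).
Passing tests on synthetic cohorts therefore demonstrate that the pipeline
recovers planted class structure of realistic effect size under realistic
noise — not that it would behave identically on scanner data with
correlated amplitudes or structured artefacts.

## Problem sizes and seeds

All randomness flows through explicit seeds; cohort generation,
bootstrapping and the pipeline are bit-reproducible given one. The test
suite runs the generator at study scale (82 and 164 spectra, 1383
datapoints), sweeps feature counts 2–6 with up to 200 bootstrap replicates
in end-to-end checks, uses 1000 replicates where bootstrap stability
itself is under test, and verifies amplitude calibration with 400
simulated spectra per class; the recovery experiment repeats the full
selection over 20 seeded cohorts. The acceptance script runs both
scenarios at full sweep ranges (2–16 and 2–20) with 1000 bootstrap
replicates.

## Known limitations

* CFS with a forced model size can admit near-duplicate datapoints of one
  resonance (see above); interpreting selected features should group
  datapoints by resonance.
* The bootstrap CCC estimates training accuracy, not generalization; the
  independent test BER is the generalization measure.
* Dichotomized metrics and AUC are computed on the training set, matching
  the workflow being modelled; they are optimistic relative to test-set
  values.
* With nine cases in the smallest class, sample medians of heavy-tailed
  amplitude distributions are noisy; per-class summaries at that size
  should be read with their IQRs.
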
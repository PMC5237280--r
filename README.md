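# mrspattern

Pattern-recognition analysis of in-vivo single-voxel proton MR spectra
(<sup>1</sup>H-MRS), built around the workflow used to derive metabolic
classifiers of brain tissue state in experimental stroke: distinguishing
non-infarcted parenchyma from the acute and subacute phases of an infarct,
and non-infarcted parenchyma from the subventricular zone (SVZ) and
infarcted tissue. It is aimed at preclinical MRS groups who want an
inspectable, scriptable version of this kind of spectral classifier — and a
synthetic cohort generator so every stage can be exercised without scanner
data.

## What it computes

Spectra are real-part intensity vectors on a 0–4.5 ppm axis (1383
datapoints by default, NMR display order). The pipeline:

1. **Normalization (UL₂CA).** Each datapoint height *h* is divided by the
   Euclidean norm of the same animal's contralateral (non-infarcted)
   spectrum and scaled to percent:

   *UL₂CA = 100 · h / √( Σ<sub>0–4.5 ppm</sub> h<sub>CA</sub>² )*

   The acquisition gain cancels, and a reference spectrum normalized to
   itself has norm exactly 100.

2. **Feature selection.** Sequential forward selection over individual
   spectral datapoints under the CFS (correlation-based feature subset)
   merit *M<sub>S</sub> = k·r̄<sub>cf</sub> / √(k + k(k−1)·r̄<sub>ff</sub>)*.
   By default relevance and redundancy are measured as symmetric
   uncertainty between MDL-discretized variables (Hall's formulation); a
   point-biserial Pearson mode is available.

3. **Classification.** Multi-class Fisher LDA on the selected datapoints:
   generalized eigenvectors of between- versus pooled within-class scatter,
   a 2-dimensional latent space for three classes, nearest-centroid
   assignment.

4. **Evaluation.** Balanced error rate
   *BER = (100/3) · Σ<sub>classes</sub> (misclassified / total)*,
   correctly-classified cases (CCC) estimated by 1000× bootstrap resampling
   of the training set, one-vs-rest sensitivity/specificity/PPV/NPV, and
   ROC AUC (Mann–Whitney, Hanley–McNeil SE). The number of features is
   swept (2–20 by default) and the model size chosen at the first local
   minimum of the test-set BER.

5. **Univariate follow-up.** Median (IQR) per class at each selected
   datapoint, Lilliefors and Levene checks, Kruskal–Wallis with Dunn's
   Bonferroni-adjusted post-hoc comparisons.

The synthetic generator (`default_config()`, `simulate_cohort()`) builds
three-class cohorts whose class-conditional peak-height distributions at
the diagnostic chemical shifts — 1.33 ppm (lactate + mobile-lipid
methylene), 3.03–3.05 ppm (total creatine), 0.85 ppm (mobile-lipid methyl),
3.62 ppm (myoinositol) — are calibrated to published median/IQR reference
values, with study-sized cohorts (48/20/14 and 48/82/34 spectra),
per-animal contralateral references, and a chronological 2/3–1/3
animal-level split.

## Worked example

```r
library(mrspattern)

cfg    <- default_config("infarct_evolution")
cohort <- simulate_cohort(cfg, seed = 42)
run    <- run_classifier(cohort, k_range = c(2, 6), n_boot = 200, seed = 42)
print(run)
#> <mrs_run> 56 train / 26 test spectra, classes: non_infarcted, acute, subacute
#>   selected_k = 3 (features at 1.33, 1.33, 3.07 ppm)
#>   test BER = 12.2%, bootstrap training CCC = 91.1 +/- 3.9%

run$confusion_test
#>                predicted
#> true            non_infarcted acute subacute
#>   non_infarcted            15     0        0
#>   acute                     1     5        0
#>   subacute                  0     1        4

summarize_feature(run$train, 1.33, by = "ppm")
#> <feature_summary> datapoint 975 (1.329 ppm), Kruskal-Wallis H = 33.7, p = 4.83e-08
#>          class  n    median      q25       q75
#>  non_infarcted 33  2.735174 2.469255  3.081851
#>          acute 14  7.314176 6.702759  8.032486
#>       subacute  9 16.389638 5.040648 19.275847
```

Reading the output: the sweep settles on a three-feature model whose
leading datapoint is the lactate + mobile-lipid resonance at 1.33 ppm (its
normalized height roughly doubles from non-infarcted to acute and again to
subacute tissue, hence the strong Kruskal–Wallis separation), followed by a
second datapoint of the same resonance and a total-creatine datapoint. The
test-set balanced error rate of 12.2% means the classifier misassigns about
one spectrum in eight, averaged evenly over the three classes.

A thin CLI with `simulate` and `run` subcommands is installed under
`inst/scripts/mrspattern`.

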
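---
title: "Methods: OPLS-DA authentication of production systems from LC-MS fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OPLS-DA authentication of production systems from LC-MS fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldprint)
```

## The problem

Untargeted LC–MS metabolomics of field crops produces a few thousand
bucket intensities per analysis. The question `fieldprint` answers is a
classification one — was this sample grown organically or conventionally? —
under an adversarial variance structure: the production-system effect is
carried by a few dozen variables at fold changes of roughly 1.2–6, while
harvest year perturbs a large fraction of the metabolome far more
strongly. Any supervised model trained across years will happily encode
year-specific variation; it then fails on a harvest it has never seen.
The pipeline's central move is therefore *deconfounding by variable
removal*: discard every variable that a year-classification model deems
important before fitting the system model, and prove the benefit with
external validation sets that hold out entire years.

## Data model and preprocessing

A `feature_table` is a samples × buckets matrix of non-negative
intensities. Each bucket is one half-open cell of a fixed RT × m/z grid —
`[lo + iΔ, lo + (i+1)Δ)` anchored at (0.5 min, 60.5 m/z) with ΔRT = 0.3
min and Δm/z = 5 mDa by default — tagged with its ionization mode and
extraction fraction. `bucket_peaks()` sums centroid-peak intensities per
cell; peaks outside the RT/m/z ranges are dropped. Boundary handling is
deliberately explicit: cell membership is decided against edges computed
as `lo + i*Δ`, so a peak sitting exactly on a representable edge always
joins the upper cell, and assignment provably matches a brute-force
interval scan (floating-point `floor((x-lo)/Δ)` alone can misplace such
peaks). Upstream vendor peak detection is out of scope; its settings
(S/N 2, correlation 0.7, minimum length 10 spectra, smoothing 2) are
carried as provenance metadata only. Buckets empty in some analyses are
zero-filled over the sparse union of occupied cells.

Two normalizations follow, in a fixed order:

* **Sum normalization** (`normalize_total()`), per analysis, *within* each
  ionization block and before blocks are column-concatenated — one
  injection is one analysis, and a per-analysis multiplier (injection
  volume, source drift) cancels exactly. The operation is idempotent.
* **Pareto scaling** (`fit_pareto()` / `apply_scaling()`):
  (x − mean)/√sd with the sample (n−1) standard deviation. This includes
  mean-centring, the convention of the chemometrics software lineage this
  field uses. Pareto is chosen over unit-variance scaling because bucket
  intensities span orders of magnitude and UV scaling would promote pure
  noise; the residual abundance weighting is a real modelling choice with
  consequences discussed under "Deconfounding". Scaled columns satisfy
  var(x') = sd(x) exactly, which the tests assert. Scaling parameters are
  fit on training samples only and frozen into every model; test and
  external samples are never self-centred.

## OPLS-DA

`opls_fit()` implements the NIPALS O-PLS recipe. For a centred response
dummy **y** (0/1, positive class = conventional) and scaled matrix **X**:
w ∝ X'y normalized; for each of `a_orth` orthogonal components the
provisional loading p = X't/(t't) is orthogonalized against w,
w_o = p − (w'p/(w'w))w, normalized, and its score t_o = Xw_o is deflated
out of X; the final predictive component is extracted from the filtered
matrix. With `a_orth = 0` this is exactly single-component NIPALS PLS1,
which the tests verify against an independent oracle to 1e−8. Predictive
and orthogonal scores are orthogonal by construction (asserted at 1e−8
relative). Multi-class responses (the year model) use one membership
column per class, the principal Y-weight direction for orthogonalization,
and `classes − 1` predictive components. Prediction applies the frozen
scaling, removes the orthogonal projections, and thresholds the predicted
dummy at 0.5 (binary) or takes the arg-max class column; the ROC sweep
explores all thresholds, so the fixed 0.5 only affects reported
classification rates.

**Component selection.** `cross_validate()` runs a sevenfold internal CV:
folds are dealt round-robin over samples ordered by class (and optional
metadata keys), so fold sizes differ by at most one and folds are
class-balanced and deterministic — Q² is bit-reproducible. Each fold
refits the Pareto scaling on its training part. Q²(cum) =
1 − PRESS/SS(Y − Ȳ) is computed for every orthogonal-component count from
0 to `a_orth_max`; `select_components()` then accepts orthogonal
components greedily while each raises Q²(cum) by more than 0.01, stopping
at the first failure. The 0.01 increment is a stated default: the
original software's significance rules are proprietary, so published
component counts are context, not targets.

## Refinement and deconfounding

VIP scores are computed from the predictive components only:
VIP_j = √(p · Σ_a SSY_a (w_aj/‖w_a‖)² / Σ_a SSY_a), so mean(VIP²) = 1
exactly — VIP > 1 means above-average importance. `filter_by_vip()` keeps
variables with VIP strictly above the threshold (ties at exactly 1.0
drop). `deconfound_factor()` fits the multi-class year model (default 2
orthogonal components, mirroring the published year model's shape),
computes its VIP, and removes the VIP > 1 set.

Two honest findings about this procedure on the generator, both asserted
in the tests at their measured levels rather than idealized ones: the
removed set recovers only a minority (~1/3) of the *planted* year-affected
variables, because Pareto scaling leaves abundance weighting in place and
the mean-VIP²=1 identity caps how many of 2400 affected variables can
exceed 1 — yet it removes essentially none of the planted system markers,
and that asymmetry is what the downstream contrast needs. Second,
refitting after VIP > 1 refinement does not increase training R²Y here
(it dips by ≲0.02): the discarded variables carry small fitted variance.
The refined model's practical value is the ~2.5-fold smaller variable set
at essentially unchanged fit, not an R²Y gain.

## Validation

`make_split()` provides the four external-validation designs: a stratified
(system × year, largest-remainder quotas) random third, leave-one-year-out,
leave-one-cultivar-out, and leave-fields-out. Any split that would empty a
class from the training set is refused. `evaluate()` reports the
classification rate, sensitivity (% conventional called conventional) and
specificity (% organic called organic); specificity is the fraud-relevant
rate, since the typical fraud is conventional produce sold as organic.
`roc()` sweeps all distinct predicted responses and integrates by the
trapezoidal rule; with ties grouped, the AUC equals the normalized
Mann–Whitney statistic to 1e−12, which the tests check exhaustively for
all labelings up to n = 6 and against an independent ROC implementation.

A systematic behavior worth knowing: on held-out *years*, deconfounded
models can show perfect ranking (AUC ≈ 1) alongside classification rates
of 65–100%, because residual year variation shifts all of a year's scores
together past the fixed 0.5 threshold. This calibration drift is why the
leave-one-year-out quality is best summarized by AUC, and why both
metrics are reported.

## Univariate confirmation

Marker candidates are the union of the S-plot tails (largest |corr(t, x_j)|)
and the top-VIP variables, 24 per route by default. Each is tested with an
equal-variance pooled two-sample t test on sum-normalized (not
Pareto-scaled) intensities — ratios are meant to be peak-area ratios of
arithmetic group means — and flagged against a Bonferroni threshold of
α/m with m the *full* refined variable count, not the candidate count:
the family of implicit comparisons is every variable the model could have
promoted. With α = 0.05 and 13250 variables this threshold is 3.77e−06.

## The synthetic generator

`generate_dataset()` emulates the study design the pipeline assumes:
`n_years = 4` harvests, `fields_per_year = 2` paired field-pairs (one
organic and one conventional field per location; `c(2, 2, 2, 1)`
reproduces a 140-sample layout), `replicates_per_field = 10`, and
`n_blocks = 3` ionization blocks of `n_variables = 2000` buckets. All
effects are additive in log2 (multiplicative on the raw scale, consistent
with fold-ratio reporting):

| quantity | default | rationale |
|---|---|---|
| baseline log2 intensity | U(10, 20) | realistic 1000-fold abundance span |
| year effect | N(0, 1.5²) log2 on 40% of variables | year must dominate the fingerprint |
| system effect | sign · U(0.5, 1.5) · 1.0 log2 on 30 markers | mean ratio 2, span ~1.4–2.8, inside the reported 1.2–6 |
| location intercept | N(0, 0.25²) log2, shared by a field pair | paired-field sampling |
| field intercept | N(0, 0.1²) log2 | within-pair heterogeneity |
| noise | multiplicative, CV 0.2 | repeatability of the assay |
| injection scale | U(0.7, 1.3) per analysis | exercised and removed by sum normalization |

System markers are disjoint from year-affected variables by default
(`markers_overlap_year = TRUE` enables the hard case). Within-field vs
between-field variance components are not reported for the real study;
the intercept sds above are stated choices, not fitted values. The
generator makes no attempt at chromatographic peak shapes, isotope
patterns or raw spectra, and its year effects are independent across
years and variables — real inter-year correlation structure (weather
gradients) is absent. Passing tests therefore demonstrate the *machinery*
(normalization contracts, deconfounding asymmetry, external-validation
accounting) under the stated variance structure, not performance on any
real harvest.

## Numerical conventions and degenerate inputs

Zero-variance variables scale to 0 (not NaN) and get S-plot correlation 0
with a flag; an all-zero analysis is an error naming the sample; a peak
list with nothing in range yields an empty row with a warning; a
confounder aliased 1:1 with the class is refused (removal would erase the
signal); zero pooled variance in the t test gives p = 1 for equal means
and an error otherwise; Q² can be negative (no predictive ability) and is
bounded above by 1. Fold assignment, splits and the generator are
deterministic given their seeds, and models serialize to plain text with
17 significant digits, enough for bit-identical re-prediction.

## Problem sizes used in the shipped checks

The end-to-end checks run at the full default design scale — 160 samples ×
6000 variables — for the random-third and leave-one-year-out validations,
and repeat the leave-one-year-out contrast (deconfounded vs not) over 20
independently seeded study replicates; module-level tests use a reduced
64 × 500 design with the same structure. On one CPU the complete suite
runs in a few minutes.
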
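---
title: "Methods: the sevmark plasma sEV biomarker workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the sevmark plasma sEV biomarker workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sevmark` implements a multimodal biomarker-discovery workflow for plasma
small extracellular vesicles (sEVs): particle-size characterization,
vibrational-spectroscopy classification, differential proteomics/miRNA
statistics, cross-cohort concordance triage, and a harmonized
machine-learning signature stage, together with a synthetic multi-cohort
generator carrying planted ground truth. This vignette explains the models
and procedures, the parameters that matter, the numerical choices, and what
the synthetic validation does and does not demonstrate.

## The synthetic study and its planted truth

Real plasma sEV cohorts of this kind are not publicly depositable, so the
package validates every stage end-to-end on simulated cohorts whose
structure mirrors the target study design:

* three cohorts — training (56 glioma cases / 48 controls), validation
  (13 cases / 20 controls plus 16 non-glioma brain tumors), and a
  longitudinal cohort (6 cases / 6 matched controls sampled over treatment);
* nine replicate infrared spectra per sample (3 wells × 3 scans), each a
  multiplicative-scatter-scaled copy of a common signal plus Gaussian class
  peaks, a well-level random intercept shared by the scans of a well, a
  sample-level intercept, an order-2 polynomial baseline and white noise;
* particle-size distributions that are log-normal in size with class
  medians 121.6 nm (case) vs 100.5 nm (control) and class totals
  1.30×10^11 vs 1.09×10^11 particles/mL, each sample varying log-normally
  around its class value;
* omics tables with planted differential features expressed in
  *within-group SD units on the log2 scale*. Proteins are log-normal
  (normal log2 abundances, per-feature baselines and SDs); miRNAs are
  negative-binomial counts stored as log2(count+1). These distributional
  forms are stand-ins — the target data's analyte distributions are not
  published — and the generated manifest labels them as such. For miRNA the
  planted shift is applied to the NB mean through a delta-method
  calibration (var log x ≈ 1/μ + 1/size), so miRNA effects are approximate
  in SD units; the exact effect-size recovery test therefore uses the
  protein modality, where planting is exact.

Planted features come in three kinds: *concordant* (same fold-change
direction in every cohort), *discordant* (direction flips in the second
cohort), and *reversed* (direction consistent across cohorts but flipped in
the non-glioma tumor group). Non-reversed planted features keep their
glioma direction in the non-glioma group, so the reversed panel is the only
set that should be flagged by the reversed-pattern analysis.

Batch effects are affine per cohort — scale then offset on the log or
intensity scale. This is deliberately the *minimal* distortion that the
workflow's chosen remedy (per-cohort z-scoring) removes exactly, which
turns harmonization into a testable identity rather than an approximation.
Missingness is missing-completely-at-random because the workflow specifies
only a detection-fraction filter, not a missingness mechanism.

Every generator draws from a single run seed with documented integer stream
offsets (see `R/synthetic_data.R`), so one `truth_config()` reproduces the
study bit-identically, and feature-level parameters sit in cohort-independent
streams so the same analytes exist in every cohort.

The longitudinal arm multiplies planted effects by 1 pre-operatively, by
`1 − attenuation` on treatment (default attenuation 0.6) and by
`recurrence_factor` (default 1.0) at recurrence, emulating markers that
normalize under therapy and re-diverge at relapse.

## Particle-size metrics

Nanoparticle-tracking exports are dense (1 nm) binned concentration
densities, so all integrals use trapezoidal quadrature on the native grid;
higher-order schemes would add nothing at this resolution. The median size
inverts the cumulative trapezoid integral with linear interpolation inside
the crossing bin. The >80 nm yield splits the threshold-straddling bin by
linear interpolation of the density, which makes the open/closed convention
at exactly 80 nm numerically immaterial. Group comparisons use Welch's
unequal-variance t test for two groups and one-way ANOVA with Tukey HSD for
three, with the conventional significance tiers (0.05/0.01/0.001/0.0001).

## Spectral preprocessing and the replicate-aware ensemble

Preprocessing follows the fixed order: truncation to 1000–3500 cm⁻¹,
extended multiplicative signal correction (EMSC), then excision of the
silent region 1801–2799 cm⁻¹ (inclusive), where no biologically relevant
bonds absorb. EMSC fits each spectrum by least squares as
`s ≈ b·r + Σ c_k·w̃^k` (reference `r`, wavenumber rescaled to [−1, 1],
order 2 — the canonical configuration) and returns `(s − Σ c_k w̃^k)/b`; any
spectrum inside that model span is restored to the reference at machine
precision, and fits with `|b| < 1e-8` are rejected as degenerate rather
than silently amplified. The EMSC reference is the mean spectrum of the
cohort the ensemble is fitted on, frozen in the model and applied unchanged
to external data, so held-out cohorts are never allowed to redefine the
correction target.

The classifier is an ensemble of 51 partial-least-squares (PLS1) regressions
on 0/1-coded labels with a 0.5 decision threshold. Each member owns a
class-stratified 70:30 split *at the sample level* — replicate spectra of
one sample never straddle a train/test boundary at either cross-validation
level, which is the property that prevents replicate leakage. An inner
sample-level stratified 5-fold cross-validation selects the PLS component
count from 1–10 (the only PLS hyperparameter) by mean replicate-level AUC.
PLS is implemented as a univariate SIMPLS kernel that returns cumulative
coefficients for every component count, so one fit scores the whole grid;
its predictions agree with an independent PLS implementation to ~1e-14 (a
test enforces this).

Consensus is hierarchical: within a member, a sample's call is the majority
vote of its replicate spectra (ties resolve to the positive class — a
screening context favors sensitivity; with 9 replicates and 51 members the
defaults are tie-free); the ensemble probability is the fraction of members
voting positive, so probabilities move in steps of 1/51. The ensemble ROC
sweeps this vote fraction as the decision score with a trapezoid AUC, which
equals pair-counting with half credit for ties. Where a sample can appear
in a variable number of outer test sets, this package always applies all 51
members to held-out data rather than restricting to members that held the
sample out; that is the documented reading of ensemble-level consensus.

Stratified splits allocate `floor(ratio·n)` training samples per class,
clamped so both classes appear on both sides; member `i` derives its RNG
stream from the run seed plus `1000 + i`.

## Differential omics statistics

Statistics run on the log2 scale (counts as log2(x+1)), matching
mass-spectrometry convention; fold changes are reported on the linear scale
with the signed convention `FC if ≥ 1 else −1/FC`, so a threshold of
"±1.5" means a 1.5-fold change in either direction. Missing values are
excluded pairwise per feature with no imputation; a feature with fewer than
two values in a compared group is flagged untestable and excluded from the
Benjamini–Hochberg adjustment's feature count. Multiple testing uses plain
BH (the upstream platforms' q-values are of unstated provenance; BH is this
package's documented choice), and a brute-force step-up implementation
serves as the oracle in the tests. Candidate tiers mirror the study's
thresholds: proteins q<0.05 (loose) and q<0.01 ∧ |FC|>1.5 ∧ unique
peptides>1 (stringent); miRNA adjusted p<0.05 (loose) adding |FC|>2
(stringent).

## Cross-cohort concordance

Concordance is defined by fold-change *direction only*: a shared feature is
concordant when its signed fold change has one sign in every cohort,
discordant otherwise, and "partial" when any cohort shows exactly no change
(|FC| = 1), where direction is undefined — assigning such features a sign
would be arbitrary. Statistical significance enters afterwards through
training-cohort tiers, matching a Venn-style triage in which direction
agreement and training significance are separate gates; whether the
non-training cohorts should also be required to reach significance is left
open by the source workflow, and direction-only is the documented choice
here. Reversed-pattern analysis compares each concordant feature's glioma
direction against a contrast comparison (non-glioma tumors vs controls) and
flags opposite signs.

## The harmonized machine-learning stage

Cohorts are harmonized by z-scoring every feature within each cohort —
exactly the transform that removes the generator's affine batch model — and
a PCA check quantifies residual cohort structure as the mean silhouette
width of cohort labels in the PC1/PC2 plane (≈0 when mixed, >0.5 for a
strong batch). Feature selection is backward recursive feature elimination,
one feature per step, scored by random-forest Gini importance; a tree-based
importance is used regardless of the final learner because kNN has no
native importance measure. Duplicated (perfectly collinear) features split
impurity importance between themselves, so which copy survives elimination
is seed-dependent; the tests probe and document this degeneracy rather than
hide it.

Three learners are compared — random forest, kNN and gradient-boosted trees
— each grid-searched with stratified 5-fold cross-validation over small
fixed grids (RF: 100/500 trees × sqrt/half feature fractions; kNN:
k ∈ {3,5,7,9,11}; boosting: 100/300 rounds × depth 2/4 × learning rate
0.1/0.3; the source workflow names grid search but no grids, so these are
the package's fixed choices). AUC is computed per fold and then averaged.
The winner maximizes mean AUC, breaking ties by the smaller AUC SD and then
by the fixed learner order; selection is fully deterministic given a seed.
An 80:20 class-stratified holdout, reserved before any selection, provides
the internal confusion matrix; external cohorts are z-scored within
themselves before evaluation (the harmonization premise), and a single-class
external cohort is scored by accuracy with the AUC reported as undefined.

### The label-shuffle chance control

The overfitting control flips the labels of a random 50% of each class
(flipping — rather than resampling — is the reading that guarantees
feature–label independence in a balanced design; with imbalanced classes
the flip differential changes class sizes, which the function reports) and
retrains the selected model. One subtlety matters: if the 10-of-100 feature
selection is run once on the shuffled dataset *before* cross-validation,
the CV estimate inherits selection bias and sits near 0.7 even though the
labels carry no information — which would defeat the control's purpose. The
control therefore nests the feature selection inside every CV fold
(`signature_cv_auc()`), giving an unbiased estimate that sits at ~0.5 under
shuffling, which is precisely the property a chance control must have. The
signature-building path keeps dataset-level RFE before training, as the
workflow prescribes; only the *estimate used as the chance reference* is
nested. Passing the winning configuration as `config` retrains exactly the
selected model; omitting it re-runs the grid search under every shuffle,
which adds a small max-over-grid optimism (~0.03–0.05) to the chance level.

## Problem sizes and what the tests show

The test suite exercises the full study conditions where they are cheap
(51 ensemble members, 1.5 SD effects, n = 100–200 per group for recovery
and chance-control checks, 10⁴ random vectors for the BH oracle) and scales
down only dimensions that do not change the property under test (coarser
wavenumber grids for split-hygiene checks, 11–15 member ensembles for null
calibration). Passing tests demonstrate that the *machinery* is correct and
calibrated — planted effects are recovered at their stated size, null
configurations produce chance-level classifiers and nominal false-positive
rates, and the leakage contracts hold exactly. They do not demonstrate
anything about real plasma sEV data: the generator's distributions are
stand-ins, its batch model is deliberately the one z-scoring removes, its
missingness is MCAR, and real spectra contain atmospheric, instrument and
scattering structure the simulator does not attempt.

## Known limitations

* Distance-weighted discrimination, platform-specific normalization
  (SomaScan/NanoString), raw mass-spectrum and read processing, and pathway
  enrichment are out of scope; inputs are assumed normalized upstream or
  produced by the generator.
* `EnsembleModel` and `Signature` objects live in memory; runs are
  reproduced from the seeded configuration (the manifest records it) rather
  than from serialized model binaries.
* kNN probabilities at small k are coarse (multiples of 1/k), which makes
  its fold AUCs slightly granular.
* The ensemble's "further consensus voting" for the ROC is interpreted as a
  sweep over the ensemble vote fraction; other readings (e.g. per-member
  ROC averaging) would differ in the tails.
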
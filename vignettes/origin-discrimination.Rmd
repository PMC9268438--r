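---
title: "Discriminating ginseng origin from LC-MS profiles: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating ginseng origin from LC-MS profiles: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ginsengms)
```

# The problem

Cultivated ginseng from Jilin (JL), Liaoning (LN) and Heilongjiang (HLJ)
shares essentially the same set of ginsenosides; what differs between
provinces is the *pattern* of their abundances. `ginsengms` implements the
full chain from per-sample MS1 peak lists to an origin call for an unknown
batch, with a synthetic-data module standing in for the (undeposited)
instrument data so that every stage has testable ground truth.

This vignette records the models, the tunable parameters and the design
decisions, in the order the pipeline runs them.

# Preprocessing

**Screening.** The acquisition workstation's rule is kept verbatim: an ion
survives if its area strictly exceeds 1000 counts, its charge state is 1,
and its quality score strictly exceeds 60. Both thresholds are strict
inequalities ("exceeding", "greater than"); `screen_peaks()` exposes them
as `min_area`, `charge`, `min_quality`.

**Alignment.** No published algorithm accompanies the peak-matching step,
so the package specifies one deterministically: all peaks from all samples
are processed in descending area order (ties by ascending m/z, RT, sample
id). A peak joins the nearest existing feature whose running-mean consensus
m/z lies within `mz_tol_ppm` (relative, default 10 ppm — Q-TOF accuracy)
and consensus RT within `rt_tol` (absolute, default 0.2 min), provided the
feature does not yet contain a peak from that sample; otherwise it founds a
new feature. Processing by descending area makes the outcome independent of
input order and lets the strongest peak win when a sample offers two
candidates. Retention-time warping is out of scope; the tolerances assume
a stable gradient (QC retention-time RSDs well under 1%).

**Common peaks.** A feature is dropped when its missing fraction is
*strictly greater* than `max_missing_frac` (default 0.8): a feature missing
in exactly 80% of samples stays. Missing cells remain 0 — no imputation —
because the Z-score treats them as genuinely low values, and the marker
stage must see the same matrix the classifier sees. Setting
`max_missing_frac` just below `1/n` reproduces the stricter
present-in-every-batch reading of a "common peak".

# Annotation

The packaged table of 69 characteristic ginsenosides stores, per record,
the retention time, elemental formula, measured adduct m/z, ion type,
reported ppm error and MS/MS fragments. `load_ginsenoside_db()` recomputes
everything that can be recomputed: monoisotopic neutral mass from the
formula (C 12 exactly, H 1.0078250319, O 15.9949146221), theoretical adduct
m/z, and the signed ppm error of the tabulated ion.

Two adduct conventions are provided because the table's own printed errors
are not consistent with a single one: the default subtracts a proton
(includes the anion's extra electron, `[M-H]- = M - 1.0072765`), the
alternative (`electron = FALSE`) uses neutral-fragment arithmetic. The
recomputed errors of all 69 records fall within 15 ppm under at least one
convention (all but a handful within 5 ppm); the package reports recomputed
values rather than forcing agreement with the printed ones. Two records are
transcribed with corrections noted in their `notes` field, where the
printed formula or ion type contradicts the record's own printed m/z and
error.

Aglycone families are assigned from the diagnostic fragment ions of the
three ginsenoside types — protopanaxatriol 475.38, protopanaxadiol 459.38,
oleanolic acid 455.35 — within a 0.05 Da window (Q-TOF mass accuracy at
fragment masses), precedence PPT > PPD > OA.

# Normalization

Mean normalization divides each feature by its across-sample mean; Z-score
normalization centers and scales each feature. The Z-score uses the
population (n) denominator by default — the transform is meant to produce
an exactly standard column, and n vs n−1 only rescales by a constant —
with `denominator = "sample"` available. Held-out samples are always
transformed with the *training* statistics (`apply_normalization()`); the
package never re-estimates normalization on test data.

# PCA and PLS-DA baselines

PCA is the eigendecomposition of the sample covariance of the
column-centered matrix, with a deterministic sign convention (the
largest-magnitude loading element is positive). PLS-DA is NIPALS PLS2
against the centered one-hot label matrix: components maximize the
covariance between the X- and Y-scores, with deflation `X <- X - t p'` so
that `X = T P' + E` holds exactly and the residual vanishes at full rank.
The default number of components is classes − 1 (= 2 for three origins).

R²Y is `1 - ||F||²/||Y||²` on the training fit. Q² comes from stratified
10-fold cross-validation: PRESS over held-out one-hot rows, with folds
seeded and training-set centering only. The permutation test refits the
model on shuffled labels and regresses R² and Q² on the correlation between
permuted and original label matrices (the unpermuted point at correlation 1
included); the intercepts at correlation 0 are the usual overfitting
diagnostic. The convention for the intercept regression is the common
chemometrics one; no claim is made that other software's intercepts are
numerically identical.

# The SVM

The core classifier is a soft-margin C-SVM solved in its dual with an RBF
kernel `K(x,z) = exp(-γ ||x-z||²)`. The solver is SMO with first-order
(maximal-violating-pair) working-set selection on a precomputed kernel
matrix, implemented in C++; it maintains `Σ αᵢyᵢ = 0` exactly and stops
when the KKT violation falls below `tol` (default 1e-3; the test suite
verifies against an exhaustive active-set enumeration oracle at 1e-9). The
bias is the mean of `y - f` over free support vectors (`0 < α < C`), which
sit exactly on the margin at the optimum, with the KKT midpoint as
fallback. The primal weight vector is only materialized for the linear
kernel; for the RBF kernel the decision function stays in its kernel
expansion.

Multiclass handling is one-vs-one with majority voting; ties break by the
larger summed signed decision value, then by class order. Hyperparameters
default to C = 1, γ = 0.03 (the values chosen for the original three-origin
model) and are otherwise selected by `grid_search()` over
C ∈ 2^{-5..15}, γ ∈ 2^{-15..3} (log₂ steps of 2) under seeded, stratified
ten-fold cross-validation, ties resolved toward the smallest C then the
smallest γ. Fold assignment deals each class's shuffled members round-robin
over folds, so folds stay class-balanced up to rounding.

The training report's "recognized" origin is the out-of-fold CV prediction
by default — every sample is predicted by a model that never saw it — with
a resubstitution mode available, since either reading is consistent with a
reported training-set accuracy.

# Permutation-importance markers

The importance value of feature k is `IV_k = s - mean_n(s_{k,n})`, with `s`
the mean stratified 10-fold CV accuracy of the configured SVM and `s_{k,n}`
the same score after independently permuting column k (repeat n of N,
default 10; every (k, n) permutation draws its own sub-seed). The raw-sum
aggregation `s - Σ_n s_{k,n}` is available behind `aggregate = "sum"` for
fidelity with the formula as usually printed, but it is dimensionally
inconsistent for N > 1 (it sums N accuracies), so the mean is the default.
The model is refit on each permuted matrix — the conservative choice — with
the fold assignment held fixed so only the permutation varies. Markers are
the features with IV strictly > 0, in decreasing order of contribution;
`refit_on_markers()` re-runs the grid search on the marker columns and
`predict_external()` classifies held-out samples from the marker panel
using training normalization statistics.

A caution from the package's own simulations: with ~30 samples, CV accuracy
moves in steps of 1/30 and is itself noisy, so the *sign* of a small IV is
unstable — permuting a pure-noise feature changes the score by a quantum in
either direction about half the time it changes at all. The IV > 0 set is
therefore best read as a *ranking* with a liberal cutoff: the planted
discriminative features reliably occupy the top ranks on synthetic data
(and a panel built from the top of the ranking classifies perfectly), but
the positive set as a whole also admits weakly-sensitive noise features.
Reproducing an exactly-six-marker outcome depends on the particular data
set and is not a stable property of the estimator at this sample size.

# The synthetic-data generator

`synthetic_spec()` emulates the aligned common-peak table of the study
design rather than raw spectra:

- **Design**: 4 LN + 8 HLJ + 19 JL training batches (the study's class
  sizes), 69 features, 6 planted origin-discriminative features. Held-out
  sets reuse the same feature universe via `sample_seed`, mirroring the
  1 LN / 2 HLJ / 5 JL market test batches.
- **Intensities**: log-normal areas, `log_mu = log(1e5)` counts. The
  log-scale noise splits into a feature-specific residual
  (`log_sigma = 0.5`, i.e. ~50% CV, the scale of batch-to-batch variability
  of individual secondary metabolites) and a small shared per-sample factor
  (`sample_log_sigma = 0.1`) for correlated injection/extraction
  variability.
- **Feature scales**: each feature is multiplied by `10^U(0, 3)` by default
  (`scale_spread = 1e3`), reproducing the orders-of-magnitude spread of
  real peak areas that makes raw-data classification fail.
- **Class signal**: the informative features are split into disjoint
  thirds; group g is shifted by `effect_size` (default 2) log units in
  class g only, so each class is separable from both others;
  `class_effect` exposes per-class multipliers for asymmetric designs.
- **Missingness**: independent Bernoulli zeros at `missing_prob = 0.02`.
  The analyzed common peaks of the study were present in essentially every
  batch, so the emulated table is nearly complete; the 0 = undetected
  convention matches the preprocessing module.
- **Peak lists**: `generate_peak_lists()` jitters each detected occurrence
  by up to 5 ppm / 0.05 min around consensus positions spaced widely across
  the 400–1700 Da / 1–32 min acquisition window, warning if jitter
  approaches half the feature spacing.

What the generator deliberately does **not** emulate: chromatographic peak
shapes, isotope envelopes, MS/MS spectra, correlated biochemical modules
(beyond the single shared intensity factor), retention-time drift, and any
class structure in the noise features. Consequently, passing tests show
that the *pipeline* behaves correctly under the stated statistical
structure — they cannot certify instrument-specific behavior on real raw
data.

# Numerical choices and degenerate inputs

- Seeds: every stochastic stage takes an explicit seed; pipeline stages
  derive sub-seeds from the master seed by a fixed affine scheme, and all
  seeds stay below 2³¹.
- SMO: kernel sub-blocks are indexed, never copied per pair; a numerically
  stuck violating pair (no representable update) terminates with the
  current iterate; non-convergence within `max_iter` is an error carrying
  the iteration count.
- Zero-variance or zero-mean features make normalization fail loudly with
  the feature named; callers drop such features first.
- Degenerate adduct masses (m/z at or below zero) warn rather than error.
- Tie-breaks are documented and deterministic everywhere: alignment
  (ascending m/z, RT, sample id), grid search (smallest C, then γ),
  one-vs-one voting (summed decision value, then class order), importance
  ranking (feature index).

# Problem sizes in the test suite

The suite exercises the study-scale design (31 × 69) for the end-to-end
properties, 20-seed replications for distributional claims (null
importances, chance-level CV, missingness concentration), and tiny n ≤ 6
problems for the exact dual-solver oracle. Strong-signal checks use
`effect_size` 3–4 with 24 informative features, where ten-fold CV accuracy
saturates; at the default 6-of-69 planting the ceiling is lower (~0.85–0.95
depending on seed), which is the realistic operating regime the marker
caution above refers to.
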
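---
title: "Methods: the two-stage periplasmic yield predictor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-stage periplasmic yield predictor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model: what is computed,
which choices were genuinely open and how they were resolved, and what a
green test suite does and does not establish.

## The prediction problem and the two-stage architecture

The input is a single amino-acid sequence: a signal peptide fused
N-terminally to the mature target protein. The output is (a) an expression
class for soluble periplasmic yield — low (≤ 0.5 mg/l), medium (0.5–100
mg/l), high (≥ 100 mg/l), boundaries inclusive at the low and high ends —
and (b) a real-valued yield in mg/l. Because observed yields span about five
orders of magnitude, a single global regressor would be dominated by the
high tail. The architecture therefore routes: a multi-class support vector
classifier assigns the class, and an epsilon-SVR trained *only on that
class's training instances* produces the yield. Misclassification is not
corrected downstream — the regressor of the predicted (possibly wrong) class
is used, and its output is clamped into the predicted class's interval, so a
routing error bounds the yield error by construction.

Class probabilities come from the one-against-one machines: each pairwise
decision value is mapped through a Platt sigmoid fitted on its own training
decision values, and the pairwise estimates are coupled into a single
probability triple (Wu–Lin–Weng second method). The predicted label is the
argmax of the coupled triple, which guarantees label/probability
consistency; the triple is reported in (High, Low, Medium) order.

## The 7,903-feature scheme

The registry is fixed and validated: 122 base features, 7,381 interaction
products, 400 dipeptide counts. Two decisions deserve explanation.

**The 122 base features are a documented reconstruction.** The scheme's
description fixes the *total* (122) and names the ingredients — length,
residue frequencies, maximum consecutive runs, group-level composition,
charge, pI, and predicted structural/kinetic properties — but not the exact
enumeration. The default registry is: length (1); per-residue frequency,
count and maximum run (60); frequency, count and maximum run of 16
documented physicochemical groups (48); absolute charge per residue (1); pI
(1); 11 predicted properties. Occurrence *counts* are included alongside
frequencies because the published feature subsets distinguish "occurrence of
tyrosine" from "occurrence frequency of tyrosine". Any edit of the group
list that changes the total fails registry validation, because the
interaction block is defined as (122 × 121)/2.

**Interactions are raw products.** An interaction feature is the arithmetic
product of the two raw (pre-standardization) base values, stored once per
unordered pair; Z-scoring is applied afterwards to the assembled vector.
Dipeptide "occurrence" is the raw overlapping count, not a frequency — the
published subset tables use both words contrastively.

**Predicted properties are pluggable stand-ins.** The original pipeline
called external predictors for folding rate, solubility, disorder,
transmembrane topology, exposure and secondary structure. Those programs are
out of scope here; the default suite substitutes deterministic
sequence-derived approximations: per-residue scale averages
(Kyte–Doolittle hydropathy, TOP-IDP disorder, Chou–Fasman propensities), a
disorder-prone residue count, a 19-residue sliding-window hydrophobic
segment count, and a square-root-of-length folding-rate law
ln k_f = 16.15 − 1.28·√L, whose log10 form satisfies the required identity
nlogPFR = logPFR·ln 10 exactly. These are *stand-ins*: they preserve the
contracts (deterministic, finite, sequence-only) and the feature-vector
shape, not the accuracy of the original tools. Users holding real predictor
output can inject it per property.

The isoelectric point solves the Henderson–Hasselbalch net-charge equation
by bisection on pH ∈ (0, 14) to 10⁻³ pH units, under the EMBOSS pKa table
(N-term 8.6, C-term 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5,
Y 10.1). Net charge is strictly decreasing in pH, so the root is unique.
Histidine counts as positive in the absolute-charge feature, consistent with
the basic/positively-charged group {H, K, R}.

## Standardization and feature selection

Features are Z-scored with the *sample* (n−1) standard deviation. Constant
features map to 0 rather than dividing by zero. Moments are fitted on
training rows only and frozen into the persisted model; prediction replays
them, so no test-set information leaks into the scaling. Selection operates
on the standardized matrix (standardize first, then select) — the
alternative order is testable by standardizing externally, but this order is
the package's contract.

CFS is implemented in its continuous (Pearson) variant: no discretization
policy is needed. For a 3-class target, the feature–target correlation is
the largest-magnitude Pearson correlation against the class signals (one
indicator per class plus the integer coding — the coding is included so that
a feature that *is* the class code scores |r| = 1). Forward search adds the
merit-maximizing feature and stops when the improvement falls below
`tie_tol` (10⁻⁶) or the subset reaches `max_subset_size` (20; all published
subsets have ≤ 7 members). Ties break toward the lowest column index, making
the search deterministic and permutation-equivariant.

A known limitation, observed in the package's own simulations: with 14–50
within-class rows and 7,903 candidates, per-class CFS frequently admits
spurious or proxy features (e.g. an interaction involving the true feature
rather than the feature itself). This is a property of correlation-based
selection at that n/p ratio, not a defect of the implementation; the
published fixed subsets (`feature_selection = "paper"`) are the safer choice
at curated-data scale.

## SVM solvers and hyperparameters

No SVM library is assumed: the binary C-SVC dual and the 2n-variable
epsilon-SVR dual are solved exactly with `quadprog`, with a 10⁻⁶ ridge on
the kernel matrix for strict positive definiteness. At the package's problem
sizes (tens of instances per machine) exact QP is as fast as SMO and has no
iteration-order nondeterminism. The intercept is averaged over free support
vectors, falling back to all support vectors.

Grid defaults follow the conventional exponential grids for the RBF kernel:
C ∈ 2^(−5..15), γ ∈ 2^(−15..3) (step 2 in the exponent), ε ∈ {0.01, 0.1, 1}
(ε in mg/l, or log10 mg/l under the log option). Grid search scores each
point by k-fold cross validation (stratified for classification), pooling
held-out predictions before scoring: macro average accuracy for SVC, RMSE
for SVR; ties go to the earliest grid point. The test suite and the
acceptance script use reduced grids of the same shape — a documented
scale-down for CPU budget, not a different search.

Stage-2 regressors fit raw mg/l within each class by default: the class
intervals already compress the dynamic range, and class-local raw-scale
errors are the convention for this architecture's reporting.
`log_scale_regression = TRUE` fits log10(mg/l) instead and exponentiates at
prediction; it is the matching model class whenever yields are believed
log-linear in the features (as they are, by construction, in the synthetic
data). Predictions are clamped to the predicted class interval with a floor
of 10⁻³ mg/l for the open low end and a cap of 10⁴ mg/l for the open high
end (above the largest curated yield, 5,310 mg/l); both are configurable.

## Evaluation machinery

Macro-averaged definitions (Sokolova–Lapalme style) are used throughout:
average accuracy is the mean per-class one-vs-rest accuracy, error rate its
complement; macro precision/recall are per-class means; macro F1 is the
harmonic mean of macro precision and recall; macro MCC is the mean of
per-class one-vs-rest binary MCCs. The generalized formulas in the source
material are unreadable figure placeholders, so these standard definitions
were adopted and are pinned by brute-force formula oracles in the tests.
Per-class ratios with zero denominators contribute 0 — this only matters in
degenerate folds. Cross-validation folds are stratified by class (with a
16-instance minority class, unstratified 10-fold CV can produce training
folds missing a class); fold ids are dealt round-robin over a class-grouped
shuffled order, so folds are balanced and k = n degenerates exactly to
LOOCV. Ablation re-runs the entire evaluation protocol — including any
hyperparameter retuning inside `eval_fn` — with each feature removed once,
and reports 100·(m_without − m_all)/m_all per metric.

## What the synthetic generator does and does not establish

`simulate_dataset()` draws uniform-composition random sequences (lengths
50–600 aa), computes a small set of planted registry features, z-scores them
within the sample, and forms a latent signal s = Σ effectᵢ·zᵢ + N(0,
noise_sd). An affine map of s onto log10 mg/l is calibrated so the empirical
quantiles at the configured class proportions (defaults 16/58/24
high/medium/low out of 98) land exactly on the 0.5 and 100 mg/l thresholds;
yields are 10^latent. Consequences: realized class counts match the
configuration up to rounding; yields span about five orders of magnitude;
with zero noise the log-yield is an exact affine function of a single
planted feature; and noise_sd is expressed in units of the unit-variance
planted signal, with the calibration fixing the final log10 scale. The
default planted set (QD dipeptide, basic-residue frequency, VT and WQ
dipeptides, and the serine × aliphatic-run interaction, effects 1–0.5,
noise 0.3) places signal inside every published task subset so each stage of
the pipeline has something to find.

What a green test on this generator establishes: the pipeline recovers
planted statistical structure — selection finds strong planted features,
the classifier separates classes driven by them, the routed regressors track
within-class yield. What it does not establish: performance on real curated
data, which depends on biological signal the generator does not emulate
(signal-peptide cleavage sites, h-region hydrophobicity, codon effects,
strain and induction conditions) and on the accuracy of the real property
predictors. The parameter-recovery checks use the strong-signal worlds
(single planted feature, effect 3, noise 0.1): a dipeptide count for
selection-by-name (it has no strong proxies among the 7,903 features) and
the continuous basic-residue frequency for within-class regression recovery
(a discrete count is constant within the extreme classes, leaving nothing to
recover there by construction), trained with the log-scale option since the
generator is log-linear.

## Numerical and degenerate-input choices

* Sequences are uppercased; non-standard letters (B, J, O, U, X, Z) are
  rejected with the record id and position, never remapped.
* Sequence length ≥ 2 is required (dipeptides need two residues).
* σ = 0 features standardize to 0; constant features correlate 0.
* PCC on constant vectors raises a variance error rather than returning NA.
* Platt sigmoids use regularized targets and a guarded Newton iteration;
  pairwise probabilities are clipped to [10⁻⁷, 1 − 10⁻⁷] before coupling.
* The QP ridge (10⁻⁶) bounds the dual solution perturbation far below any
  reported digit at these problem sizes.
* Model bundles are versioned JSON text with a base64-wrapped binary
  payload: loading a bundle reproduces predictions bit-for-bit, and a newer
  format version is refused explicitly.
* Splits, folds, grid search and simulation derive all randomness from
  explicit integer seeds via scoped RNG (the caller's RNG state is never
  disturbed).

## Known limitations

* The default property suite is a stand-in; absolute feature values for the
  11 predicted properties differ from the original external tools, so models
  trained with the defaults are not comparable to models trained on real
  predictor output.
* Per-class CFS is unreliable below ~50 rows (see above).
* Platt calibration uses training decision values rather than
  cross-validated ones — adequate for the contracts (normalization, argmax
  consistency), slightly overconfident as probabilities.
* The high-class cap (10⁴ mg/l) truncates genuinely extreme constructs; it
  exists to keep the open interval bounded and is configurable.
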
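---
title: "Stacked ensemble QSAR classification: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ensemble QSAR classification: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Given a table of compounds — SMILES structures with IC50 potencies against a
protein target — the package builds a binary classifier that predicts whether
a new compound is an inhibitor (active) or not. The approach is stacked
generalization with two layers:

1. **Base layer.** Each of up to nine molecular fingerprint families
   (`AP2D`, `AP2DC`, `KR`, `KRC`, `MACCS`, `Pubchem`, `FP4`, `FP4C`, `RDK5`)
   is paired with each of up to eight classification algorithms (`RF`, `GLM`,
   `SVM`, `XGB`, `KNN`, `PLS`, `CART`, `MLP`), giving up to 72 grid-tuned base
   classifiers.
2. **Meta layer.** For every base classifier we form a *probabilistic
   feature* (PF): the training rows are split into k = 10 stratified folds,
   and each row's PF value is the active-class probability predicted by the
   base classifier trained on the other nine folds. The full PF matrix (the
   72-dimensional *APF*) is then filtered by a two-step selection — random
   forest importance ranking followed by an incremental top-m search scored
   by cross-validated MCC — and an RBF-kernel SVM (the meta-classifier) is
   trained on the selected columns (the *OPF*).

The out-of-fold construction is what makes the meta layer honest: every PF
entry comes from a model that never saw that row's label, so the meta SVM is
trained on predictions of the same character it will receive at deployment
time. For new compounds, PF values come from the base classifiers refit on
the full training split (standard stacked-generalization deployment; a
configuration flag switches to averaging the ten fold models instead).

A documented ambiguity: the PF could also be read as the pointwise average
of ten fold models each predicting *all* training rows. We implement both
behind `pf_mode`, but default to the out-of-fold concatenation, because the
averaging reading lets nine of ten models see each row's label and produces
optimistically biased meta-features.

## Curation

Raw tables (generic CSV or ChEMBL bioactivity-export dialect) are normalized
to `id`, `smiles_raw`, `ic50_nM`. Units are converted where unambiguous
(pM–M); other units drop the row with a warning. Structures are desalted by
keeping the largest carbon-containing component, canonicalized with
OpenBabel, and deduplicated by canonical SMILES with the **median** IC50
retained — the median is robust to the order-of-magnitude assay outliers
common in public bioactivity data. Labels use the conventional potency
thresholds: active at IC50 ≤ 1,000 nM, inactive at ≥ 10,000 nM,
intermediate in between (excluded from modeling). Both thresholds are
arguments of `label_thresholds()`.

The train/test split is stratified *per class*: exactly
`floor(0.8 · class_size)` compounds of each class go to training. This
per-class floor convention reproduces the usual published count arithmetic
exactly (e.g. 1,145 actives / 851 inactives → 916 + 229 and 680 + 171),
which a global 80% draw does not guarantee.

## Fingerprints

Widths are fixed by the family registry: AP2D(C) 780, KR(C) 4,860, MACCS
166, Pubchem 881, FP4(C) 307, RDK5 2,048; the `*C` families are substructure
counts, the rest presence bits. Two families are computed natively:

* **MACCS** via OpenBabel's 166 structural keys. We verified on reference
  molecules that OpenBabel's on-bit key numbers coincide with RDKit's, and
  the test suite cross-checks against RDKit as an independent oracle.
* **RDK5-family** hashed path fingerprint, implemented in this package: all
  simple bond paths of length 1–5 are enumerated on the molecular graph,
  each path's canonical element/bond-order string (the lexicographically
  smaller read direction) is hashed with FNV-1a into 2,048 buckets. This is
  a faithful member of the Daylight-style hashed-path family — width and
  maximum path length as specified — but bit positions are not interchangeable
  with RDKit's own hashing.

The remaining seven families are accepted through validated import of
PaDEL-Descriptor CSV output (exact width, value-kind and row-alignment
checks; binary blocks must be strictly 0/1). Re-deriving the thousands of
SMARTS definitions behind those families would duplicate a reference tool
without adding information, and import preserves bit-exact compatibility.
Zero-variance columns are kept at full width; only distance/projection-based
learners (KNN, PLS) drop constant columns internally, with the mask stored
for prediction.

## Tuning and evaluation

Each base classifier is tuned by exhaustive search over a small grid
(defaults in `default_grid()`: e.g. RF features-per-split ∈ {√p/2, √p, 2√p}
at 500 trees; SVM cost ∈ {0.1, 1, 10} with γ ∈ {1/p, 10/p}; KNN
k ∈ {3, 5, 7, 9}), scored by stratified k-fold cross-validated MCC with
pooled out-of-fold predictions; ties take the first candidate in enumeration
order. Inside the PF construction, each fold model is tuned on its own
nine-fold training part with an inner 5-fold CV (the inner fold count is a
runtime choice; a single-candidate grid skips the inner CV entirely).

Six metrics are reported: ACC, BACC = (Sn + Sp)/2 (an exact identity in the
code), Sn, Sp, MCC, and rank-based AUC (the normalized Mann–Whitney U, ties
counting one half, equivalent to exhaustive pair counting). Numerical
conventions: MCC is defined as 0 whenever a marginal of the confusion table
is empty; the classification threshold is fixed at 0.5; CV reports pool the
out-of-fold predictions (micro-averaging) rather than averaging per-fold
metrics — pooling matches the PF construction and avoids undefined per-fold
MCC on small folds (macro averaging is available via `cv_scoring`).

## Two-step selection

Step 1 ranks PF columns by impurity-decrease importance from a 500-tree
random forest (permutation importance available); ties break by column
order. Step 2 evaluates nested top-m subsets over an arithmetic grid of
sizes, scoring each with an RBF SVM under one shared stratified fold plan —
sharing the plan across m makes score differences attributable to the
feature sets rather than fold luck. The argmax is chosen, preferring the
smaller m on ties (parsimony). The scoring SVM uses fixed parameters
(cost 1, γ = 1/m); only the final meta-classifier is grid-tuned, since
re-tuning inside the subset search would nest three levels of
cross-validation for no measurable ranking benefit.

The default size grid is (m_start, m_end, s) = (5, 70, 5), i.e. n = 14
candidate sizes. The method description this grid descends from states
m_end = 50 together with n = 14, which is internally inconsistent
(5..50 by 5 gives 10 sizes); we resolve the conflict in favor of n = 14 and
expose all four values in the configuration.

## The synthetic generator

`gen_labeled_smiles()` emulates a curated ChEMBL-style input: unique
molecules built from simple scaffolds (benzene, cyclohexane, biphenyl, aryl
ketone) decorated with either activity motifs (trifluoromethyl/difluoro,
N,N-dialkylamine — groups of the kind that dominate real feature-importance
analyses of ER inhibition) or neutral alkyl/ether groups; IC50 values drawn
uniformly inside U(10, 900) nM for actives and U(12,000, 90,000) nM for
inactives, safely inside the default thresholds; optional salt adducts,
duplicate rows and unparseable SMILES at configurable rates. `label_noise`
draws a fraction of compounds' IC50 from the *opposite* class range, which
decouples label from structure exactly as assay noise does.
`gen_fp_block()` fabricates registry-width PaDEL-style matrices in which a
chosen fraction of columns tracks the class label with a per-bit flip rate.

What the generator does *not* emulate: real scaffold diversity, correlated
fingerprint bit structure, activity cliffs, or assay heterogeneity. Passing
the synthetic experiments therefore demonstrates that the machinery recovers
plantable signal without leaking labels — not that any particular real-world
accuracy will be achieved.

## The desk-scale experiments

`planted_motif_experiment()` is the package's standing validation: 600
compounds (300/300) with 10% label noise, three descriptor families (native
MACCS carrying the real motif signal; an imported FP4 block with six
label-linked columns at per-bit flip 0.3; an imported AP2D block of pure
noise) and four fast base algorithms (RF, GLM, CART, KNN) with
single-point grids, k = 10. It reports each base classifier's out-of-fold
CV MCC, the meta SVM's CV MCC on the selected columns under a fresh fold
plan, and whether the importance ranking placed all eight informative PF
columns (those fed by MACCS or FP4) above every null column. Recovery is
deliberately defined on the *ranking*: the four algorithms' PF columns per
family carry near-identical information, so the CV argmax of step 2
legitimately settles on a smaller subset than the full redundant eight; the
scientific claim under test is that step 1 separates signal from noise.
`null_signal_experiment()` repeats the shape with all-noise blocks and
checks that every CV MCC estimate sits inside the ±0.15 sampling band.

Problem sizes throughout (600-compound fixtures, 5–10 folds, 300–500 trees,
single-point experiment grids) were chosen so a full validation cycle runs
in minutes on one CPU while keeping every class count large enough for
stable stratified folds.

## Known limitations

* Canonicalization dialect differs between toolkits; curating the same raw
  ChEMBL export with a different standardizer can change duplicate collapse
  and hence dataset counts.
* The RDK5-family bits are not interchangeable with RDKit's hashing, so
  models trained on one implementation cannot score fingerprints from the
  other.
* Published hyperparameter grids for the original 72-classifier matrix are
  not reproduced here; the defaults are sensible small grids, fully
  overridable, and no claim of exact hyperparameter reproduction is made.
* Tautomer handling is limited to OpenBabel's canonicalization; no explicit
  tautomer enumeration is performed.
* Reproducing published ChEMBL-scale performance numbers requires the
  original datasets and is outside the desk-scale validation surface.
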
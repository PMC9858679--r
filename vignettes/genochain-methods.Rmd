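---
title: "Methods: multi-label genetic disorder prediction with classifier chains and stacked tree probabilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-label genetic disorder prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Clinical-genomic registries of paediatric patients record dozens of mixed
categorical/numeric attributes (inherited-gene flags, maternal history,
blood counts, symptoms) together with *two* diagnostic labels: the
aetiological **genetic disorder** (mitochondrial, multifactorial, or
single-gene inheritance; 3 classes) and the **disorder subclass** (nine
diseases, e.g. Leber's hereditary optic neuropathy, cystic fibrosis,
Tay-Sachs). Predicting both labels jointly is a *multi-label multi-class*
problem: the label variables are correlated — every subclass belongs to
exactly one aetiological group — and a model that predicts them
independently can emit clinically impossible pairs (e.g. "mitochondrial
disorder" with "cystic fibrosis").

`genochain` implements a complete, reproducible pipeline for this problem:
schema-driven I/O, a fixed encoding dialect, class rebalancing by
undersampling, a from-scratch classifier chain, a stacked
probability-feature constructor, the Jaccard-family multi-label metrics,
and a synthetic patient-table generator that makes every component testable
without access to any proprietary registry.

## Preprocessing and encoding

The column registry (`genome_schema()`) is the single source of truth: 44
required columns, two of which are the targets, plus the optional
identifier `Parental consent` that some exports carry. Thirteen columns are
dropped before modelling (`dropped_columns()`): identifiers and free text,
the laboratory columns Test 1/2/3/5 (Test 4 is retained), and the autopsy
indicator. The categorical encoder applies a fixed integer dictionary over
the alphabet {−1, 0, 1, 2} (`encoding_maps()`), e.g. Yes/No → 1/0,
`Not applicable` → −1, `Ambiguous` gender → 2, and all three of
`No record`/`Not available`/`No` birth-asphyxia states collapse to 0 — the
last two deliberately indistinguishable, as printed in the source dialect.
Remaining nulls in features become 0. Rows with a null in either *target*
are excluded (not zero-filled): a zero-filled label would manufacture a
spurious class, and roughly a third of the emulated registry is unlabelled.

Class imbalance (the disorder classes occur at roughly 51%/10%/38%) is
addressed by random undersampling to the minority count
(`balance_undersample()`), applied to the disorder label only. Splitting
(`train_test_split()`) defaults to stratification on the joint
(disorder, subclass) cell; the source procedure does not state whether its
splits were stratified, and stratification stabilises the 9-way subclass in
small test partitions. `stratified = FALSE` mimics a plain split. Whether
balancing precedes splitting is likewise unstated; the grid runner defaults
to balance-then-split (matching the narrative order of the procedure) with
`split_then_balance` available.

## The classifier chain

The chain runs over the **12 binarized classes** (3 disorder + 9 subclass
one-hot columns), not over the 2 label variables: the source description
sets the number of chained classifiers equal to the number of classes. The
alternative reading — a two-stage chain over the label variables — is
genuinely plausible and is provided as `fit_categorical_chain()`.

Member *k* is a binary classifier trained on the input features plus the
*true* indicators of all preceding classes in the chain order (classic
classifier-chain training); at inference it consumes the preceding members'
*predicted* hard indicators, so member input widths form the ladder
d, d+1, …, d+11. The default order puts the three disorder classes first so
that every subclass member can condition on the predicted aetiology.
Decoding (`decode_labels()`) takes the argmax of member scores within each
block, ties broken toward the lowest class index; degenerate raw
indicators (zero or multiple positives per block) therefore always resolve
to exactly one class per label.

## Stacked probability features

The hybrid feature constructor (`fit_etrf()`) fits an extra-trees and a
random-forest model per target (four models) and concatenates their class
probability vectors into a 24-column feature set, block order
ET-disorder(3), ET-subclass(9), RF-disorder(3), RF-subclass(9). Whether the
original procedure produced training-row probabilities in-sample or
cross-validated is unstated; the default here is **out-of-fold** with 5
folds — training rows receive probabilities from models that never saw them,
the standard stacked-generalisation guard against leakage — with
`mode = "in_sample"` available for fidelity to the source's apparent
behaviour. Both targets feed the stack because the downstream task predicts
both labels. By default the hybrid set *replaces* the raw features
(`append_raw = TRUE` concatenates instead).

## Base learners

Five learners are registered: `DTC` (single exhaustive-split CART), `RFC`
(100 bootstrapped trees, √p features per split), `ETC` (300 unbootstrapped
random-threshold trees, √p features), `LR` (l2 logistic regression), and
`KNN` (k = 5, uniform votes, Euclidean). The tree ensembles are implemented
in compiled code inside the package (Gini impurity, depth cap 300,
midpoint thresholds for exhaustive splits, uniform random thresholds for
extra-trees) because no tree-ensemble package is available in the target
environment; their hyperparameters follow the published configuration
table. `LR` emulates a C = 1 l2-penalised logistic regression via a ridge
path warm-started down to λ = 1/n (a single small λ can stall the
multinomial solver). The published configuration also lists MLP, XGB and
SVC; these are not registered because no corresponding implementation is
available offline, and no package contract depends on them.

## Evaluation metrics

On the n × 12 indicator pair, with per-row true set Y and predicted set P:

* **Hamming loss** = (1/nL) Σ [y ≠ ŷ]: the fraction of wrong column
  decisions.
* **Row-Jaccard accuracy** (example-based macro accuracy) =
  mean |Y ∩ P| / |Y ∪ P|.
* **Label-based macro accuracy** = per-column binary accuracy averaged over
  columns. The source text describes the label-based variant while its
  printed formula is example-based; both are computed and reported
  (`macro_accuracy_label_based`, `macro_accuracy_example_based`), and the
  replica table view uses the label-based one matching the prose.
* **α-evaluation score** = mean (1 − (β·|FN| + γ·|FP|)/|Y ∪ P|)^α, the
  generalized Jaccard similarity, base clipped at 0, defaults
  α = 1, β = γ = 1 (at which it is algebraically identical to row-Jaccard).
  The printed formula in the source is typographically garbled; the
  implementation follows its verbal definition (FN = missed true labels,
  FP = false alarms) and the canonical form from the multi-label
  literature. Rows with an empty union score 1 — unreachable under the
  one-hot encoder but the standard convention for a general metric library.
* **Per-label precision/recall/F1** are one-vs-rest, macro-averaged over
  classes by default (micro and support-weighted variants available);
  the averaging scheme is not named in the source, macro is the
  conventional choice for imbalanced medical data. Zero-division cells
  score 0 with a warning.

## The synthetic generator

`generate_patients()` emits full-schema tables under a stated world:

* **Priors** default to 10202/2071/7664 ÷ 19937 — the published imbalanced
  disorder proportions.
* **Hierarchy**: the subclass is drawn uniformly within the disorder's
  group. The 3×3 partition (mitochondrial: Leber's, Leigh, mitochondrial
  myopathy; single-gene: cystic fibrosis, Tay-Sachs, hemochromatosis;
  multifactorial: diabetes, cancer, Alzheimer's) follows standard clinical
  genetics — the source does not state one — and is overridable.
* **Missingness** per column equals one minus the published per-feature
  record count over 31,548 rows (e.g. maternal gene ≈ 0.207). Labels are
  exempt by default; `label_nulls = TRUE` exercises the exclusion path.
* **Scenarios** fix the feature–label dependence: `separable` plants
  wide-margin deterministic rules (white-blood-cell-count intervals for the
  disorder, patient-age intervals for the subclass, redundant gene flags);
  `noisy_linear` is the same layout with Gaussian overlap, disorder
  moderately noisy and subclass strongly noisy so the hierarchy carries
  exploitable information; `nonlinear_interaction` encodes the disorder in
  the sign product of two columns and the within-group index in another
  product, so linear learners sit near chance while tree ensembles succeed;
  `independent_labels` severs the disorder–subclass coupling.

Numeric marginals are stylised (uniform/normal draws over the published
ranges), not fitted; inter-feature correlations of real registries are not
reproduced. A green test on this generator therefore establishes
*algorithmic* correctness — encoding, chaining, stacking, metric algebra,
determinism — not clinical performance on any real registry.

## Numerical choices and edge cases

* All randomness flows from explicit integer seeds; no function perturbs
  the caller's RNG state. Grid arms derive their seeds from the master seed
  by a documented stable string hash, so any arm is reproducible alone.
* Constant indicator columns yield constant chain members (with a warning)
  rather than failures; empty prediction inputs yield empty outputs.
* Decoding ties break toward the lowest class index; an all-zero block
  decodes to class 0.
* The grid CSV omits wall-clock training time so repeated runs are
  bit-identical; timing stays in the in-memory reports, informational only.
* Exact recovery on the separable scenario is a fixed-seed contract:
  exhaustive-split trees place decision boundaries at training-data
  midpoints, so under an arbitrary seed a test point falling outside the
  training range of a signal feature can be clipped. The acceptance test
  pins the stated seed and demonstrates recovery through both routes (tree
  learner on raw features; linear learner on the stacked probabilities).

## Known limitations

* The learner registry omits MLP, XGB and SVC (no offline implementation);
  the experiment grid consequently covers five of the eight published
  learners.
* The compiled CART ensembles match the published hyperparameters but are
  not bit-compatible with scikit-learn's trees (different tie-breaking and
  RNG), so published table values would not reproduce exactly even with
  the original data — which is in any case not redistributable.
* `Parental consent` appears in the published drop list but not in the
  44-column schema listing; the registry carries it as an optional
  identifier column and tolerates its absence, so encoded width is
  30 features when it is present (45-column table) — the two published
  counts cannot both hold at once.
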
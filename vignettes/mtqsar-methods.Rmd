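---
title: "Multitarget QSAR and proteochemometric modelling with mtqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitarget QSAR and proteochemometric modelling with mtqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The modelling problem

`mtqsar` predicts chemical–protein interactions (CPIs) as binary
active/inactive calls. For a panel of protein targets, each with a curated
set of compounds carrying half-maximal inhibitory concentrations (IC50),
the package trains a named suite of classifiers per target and combines
their votes into a single interaction call. Two model families are
involved:

* **Per-target fingerprint models.** For every target, eight classifiers —
  the cross of four learners (random forest, support vector machine,
  k-nearest neighbours, neural network) with two compound representations
  (166-bit MACCS structural keys and a 1024-slot counted
  extended-connectivity fingerprint of radius 3, "ECFP6").
* **Pooled proteochemometric (PCM) models.** Eight more classifiers of the
  same learner/fingerprint cross, trained once on the union of all
  targets' training sets. Their feature vector concatenates the compound
  fingerprint with a protein descriptor block, so one model serves every
  target: `x = [fingerprint | projected protein descriptors]`.

A suite over `T` targets therefore holds `8T + 8` classifiers, and any
(compound, target) query is answered by exactly 16 of them — the target's
own eight plus the eight PCM models evaluated with that target's protein
block. A pair is called **active** when at least `cutoff` of the 16 votes
are positive; the default cutoff of 9 is where the cutoff sweep (below)
places the accuracy optimum on pooled held-out data.

# Curation

Raw records `(compound_id, smiles, ic50, target_id)` pass through:

1. **Standardization** — the largest covalent fragment is kept (salt
   stripping, ties broken by lexicographically smallest canonical SMILES),
   formal charges are neutralized where chemically valid, and the result
   is canonicalized. The operation is idempotent; unparseable SMILES are
   skipped and logged. OpenBabel (via ChemmineOB) is the chemistry
   backend, so "canonical" means OpenBabel-canonical.
2. **pIC50 conversion** — `pIC50 = -log10(IC50 in mol/L)`; file-level unit
   declaration (`M` default, `nM` accepted).
3. **Deduplication** — one record per canonical structure; conflicting
   duplicate activities keep their *median* pIC50, which is robust to
   single outlying assay values.
4. **Threshold selection** — the activity threshold is not fixed at a
   conventional value but chosen from a candidate grid (default 4.0 to 9.0
   in 0.5 steps) to minimise the class imbalance `|#active − #inactive|`,
   with ties broken toward the smallest candidate (favouring actives).
   This makes "a balanced distribution of active and inactive compounds"
   a deterministic, reproducible rule.
5. **Labelling** — `active` iff `pIC50 ≥ threshold`. The boundary is
   *inclusive*; this convention is stated once and asserted everywhere.
   Compounds whose duplicate measurements straddle the threshold while
   their median sits within ±0.3 pIC50 of it are dropped as ambiguous —
   their label would be an artefact of the aggregation rule.

Only exact IC50 values are expected; qualified measurements (">", "<")
should be excluded upstream. Datasets smaller than 40 records after
curation are flagged: classifiers built from them have a narrow
application domain.

# Features

**MACCS keys** come from OpenBabel's 166-key implementation.
**ECFP6 counts** are computed by the package itself, because no installed
R toolkit produces *counted* circular fingerprints: atoms start from an
invariant hashing their element, heavy degree, bond-order sum and formal
charge; three rounds of neighbourhood rehashing (sorted
(bond-order, neighbour-invariant) pairs) produce one identifier per atom
per radius, and identifier counts are folded modulo 1024. Canonicalizing
the input before graph construction, plus the order-independent
neighbour sort, makes the fingerprint invariant under SMILES re-spelling;
hash collisions between environments are accepted, as in any folded
fingerprint.

**Protein descriptors** cover amino-acid composition (20), dipeptide
composition (400), optional tripeptide composition (8000) and
composition/transition/distribution descriptors (147) over the seven
canonical physicochemical groupings (hydrophobicity, normalized van der
Waals volume, polarity, polarizability, charge, secondary structure,
solvent accessibility; three classes each). The default family set
(AAC + DPC + CTD, 567 features) keeps the block compact; enabling TPC
brings the inventory to 8567, matching the scale of classic descriptor
suites.

The protein block is min-max normalized and PCA-reduced *before* being
concatenated with fingerprints. Both transforms are fit once on the
target panel and frozen; out-of-range values at predict time are clipped
to [0, 1], and constant features map to 0. The configured 150 components
are capped at the rank bound `min(150, T − 1, features)` — with 15
targets only 14 components can carry variance, so the cap is reported
rather than padded. With random synthetic sequences the protein block can
act only as a target identity encoding, which is exactly the information
a pooled model has available when the panel is small.

# Models

Hyperparameters (all overridable through the `models` configuration
section, defaults logged in the suite):

| learner | defaults | notes |
|---|---|---|
| RF | 500 trees, unlimited depth | raw count fingerprints |
| SVM | RBF kernel, C = 1, γ = 1/d, Platt-scaled probabilities | min-max scaled inputs |
| KNN | k = 5, Euclidean | min-max scaled inputs |
| NN | 1 hidden layer, 16 rectified units, 300 full-batch Adam epochs, lr 0.01, L2 1e-4 | min-max scaled inputs |

Tree ensembles see raw counts; distance- and margin-based learners see
min-max scaled features, since their geometry is scale-sensitive. Every
learner exposes a positive-class score in [0, 1]; the binary vote is
`score ≥ 0.5`.

The neural network is implemented in the package as a single-hidden-layer
perceptron trained by full-batch Adam on the logistic loss. This is a
deliberate design choice: quasi-Newton trainers maintain an approximate
Hessian that grows quadratically with the weight count, which is
impractical at fingerprint dimensionality (a 1024-input network already
carries ~10^4 weights); a first-order optimizer with BLAS matrix algebra
trains the same architecture in seconds, deterministically under its
seed.

Reproducibility: a single master seed fans out to named sub-seeds
(`derive_seed(master, name)`, a stable string hash) for every split, fold
plan and model fit, so the full build is bit-reproducible and independent
of stage ordering.

# Validation

Each target's set is split 80/20 by stratified sampling; 5-fold stratified
cross-validation runs inside the training partition. Fold sizes differ by
at most one overall *and* within each class. Out-of-fold predictions are
**pooled** into a single confusion table before computing metrics —
averaging per-fold Matthews coefficients is ill-defined when small folds
produce degenerate tables, while pooling always is. The choice is recorded
in the report metadata (`partition = "cv"` rows).

Metrics: SE = TP/(TP+FN), SP = TN/(TN+FP), Q = (TP+TN)/N,
MCC = (TP·TN − FN·FP)/√((TP+FN)(TP+FP)(TN+FN)(TN+FP)), and ROC AUC as the
Mann–Whitney probability that a random positive outscores a random
negative (ties = ½). Any ratio with a zero denominator is 0 by declared
convention — tested, not assumed.

# The cutoff sweep

`sweep_cutoffs()` thresholds vote counts at every cutoff 1–16 and reports
SE, SP, Q, MCC per cutoff. Because the positive set at cutoff c+1 is a
subset of the positive set at cutoff c, SE is non-increasing and SP
non-decreasing in the cutoff — an exact property, asserted for every
sweep. Two "AUC"-like quantities are reported: the sweep's `AUC` column
is the balanced accuracy (SE+SP)/2 of the thresholded calls at that
cutoff (the quantity that tracks Q on balanced sets), while the orthodox
ranking AUC of the vote count used as a 0–16 score is attached once as
`vote_auc`. Keeping both avoids conflating a per-cutoff quantity with a
ranking quantity.

The call rule is **inclusive**: active iff `vote_count ≥ cutoff`. A
strict reading ("more than nine of 16") is sometimes seen for ensemble
voting; we implement ≥ and expose the cutoff, so a strict caller can use
`cutoff + 1`.

# The synthetic benchmark

Real activity panels require database extracts; the generator replaces
them with a fully specified, reproducible stand-in:

* **Molecules** come from a fixed grammar of chain-safe SMILES fragments
  (every fragment starts and ends on an atom with spare valence, so
  concatenation always parses): ~24 background scaffolds/linkers and 32
  distinctive decorated rings reserved as signatures.
* **Targets** own two signature fragments each, disjoint across targets,
  plus a random 200–600-residue sequence.
* **Activities**: each compound includes a signature fragment with
  probability ½; signature carriers draw pIC50 from N(μ₀+δ, σ), the rest
  from N(μ₀, σ), with μ₀ = 4.5, δ = 3, σ = 0.5. At these defaults the
  expected rate of labels crossing the midpoint against their fragment
  status is 2(1 − Φ(δ/2σ)) ≈ 0.27%, so the planted signal dominates and
  learners that read substructure from fingerprints can recover it; the
  bimodal pIC50 distribution hands the curation stage a balancing
  threshold near μ₀ + δ/2.
* **Ground truth** is the fragment-membership matrix: a pair is positive
  iff the compound carries one of the target's signature fragments, so a
  compound can be positive for several targets.

What the generator does *not* emulate: real chemotypes and scaffold
diversity, heterogeneous assay noise, activity cliffs, correlated targets
and homologous binding sites, or informative protein sequences. Passing
tests on the benchmark therefore demonstrates that the machinery is
correct and that planted structure–activity signal is recovered — not
that any particular real-world panel would reach the same figures.

# Experiment sizes

The package's own reference experiments, used by the test suite and the
acceptance script, are sized as follows: suite-cardinality checks build
15 targets × 200 compounds with default hyperparameters; the
signal-recovery benchmark is 5 targets × 400 compounds (default
hyperparameters, fixed seed), on which every per-target RF/KNN/SVM model
is expected to exceed held-out AUC 0.75 and the cutoff-9 ensemble
accuracy 0.80; the interior-optimum experiment regenerates a compact
3 × 120 benchmark under 20 seeds with a lean model configuration
(100 trees, 120 NN epochs) and checks that the argmax-Q cutoff falls
strictly inside 1–16 in at least 90% of runs. These sizes are the
package's chosen reference conditions; all of them scale up through
configuration.

# Numerical and degenerate-input choices

* Constant features scale to 0; out-of-range values clip to [0, 1].
* Zero-denominator metric ratios are 0; MCC of a degenerate table is 0.
* Threshold ties in curation go to the smallest candidate; fragment-size
  ties in salt stripping go to the lexicographically smallest canonical
  SMILES; argmax ties in the cutoff sweep resolve to the smallest cutoff.
* Records exactly at the activity threshold are active.
* A single-target suite has no usable protein variance; its PCM block
  degenerates to a constant column and the pooled models reduce to
  fingerprint models — the cardinality contract (8·1 + 8) still holds.
* Classes with fewer than two members refuse to split; folds refuse
  k larger than the smallest class.

# Known limitations

* OpenBabel's MACCS and canonicalization conventions differ in detail
  from other toolkits'; fingerprints are internally consistent but not
  bit-compatible across toolkits.
* The ECFP6 dialect (invariants, hash, folding) is the package's own;
  like all folded fingerprints it admits collisions.
* The balance-driven threshold adapts to each dataset, so thresholds are
  not comparable across targets with very different potency ranges.
* PCM models gain over per-target models only when protein descriptors
  carry transferable signal; with few targets or uninformative sequences
  they act as identity-encoded pooled models.
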
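# mtqsar — multitarget QSAR and proteochemometric prediction of chemical–protein interactions

`mtqsar` is an R toolkit for panel-scale bioactivity classification: given
activity records (compound, SMILES, IC50) for a set of protein targets, it
curates each target's records into a balanced binary classification set,
trains a named suite of classifiers, and calls chemical–protein
interactions (CPIs) by a multivoting ensemble. It is aimed at
cheminformatics practitioners who want a reproducible, scriptable
alternative to ad-hoc per-target modelling when screening compound
libraries against a disease-associated target panel.

## The method

For each target *t* in a panel of *T* targets:

* records are salt-stripped, canonicalized, converted to
  pIC50 = −log₁₀(IC50 [mol/L]), deduplicated (median pIC50 on conflict),
  and labelled *active* iff pIC50 ≥ θ, where θ is chosen from a candidate
  grid to minimise |#active − #inactive|;
* eight classifiers are trained on a stratified 80/20 split of the set:
  {RF, SVM, KNN, NN} × {MACCS (166 bits), counted ECFP6 (radius 3, 1024
  slots)}.

Across the panel, eight more *proteochemometric* (PCM) models are trained
on the pooled training sets, with feature vector
`[fingerprint | protein block]`, where the protein block is the target's
sequence descriptors (amino-acid/dipeptide composition + CTD), min-max
normalized and PCA-reduced to `min(150, T − 1)` components. The suite
holds `8T + 8` classifiers; every (compound, target) query receives
exactly 16 binary votes and is called active when

```
vote_count ≥ cutoff        (default cutoff = 9)
```

Model quality is reported as SE = TP/(TP+FN), SP = TN/(TN+FP),
Q = (TP+TN)/N, MCC = (TP·TN − FN·FP)/√((TP+FN)(TP+FP)(TN+FN)(TN+FP)) and
ROC AUC (Mann–Whitney, ties = ½), under 5-fold cross-validation and on
the held-out split. The ensemble cutoff is calibrated by sweeping 1–16
and examining the SE/SP trade-off; active calls export directly to
compound–target networks (SIF/GraphML).

A synthetic chemogenomics generator ships with the package: molecules are
assembled from a fragment grammar, each target plants distinctive
signature fragments whose carriers are ~1000× more potent, and the
ground-truth interaction matrix is known — so the full pipeline is
testable end-to-end without any database exports.

## Worked example

```r
library(mtqsar)

bm <- generate_benchmark(n_targets = 3, n_compounds_per_target = 150, seed = 7)
print(bm$datasets[["T01"]])
#> <activity_dataset> target T01: 150 compounds (75 active / 75 inactive), threshold pIC50 >= 5.50

suite <- build_suite(bm$datasets, bm$registry,
                     list(seed = 7, models = list(rf_ntree = 200L)))
print(suite)
#> <model_suite> 3 target(s), 32 classifiers (24 per-target + 8 pooled PCM)

report <- evaluate_suite(suite, partitions = "test")
head(report[report$algorithm == "RF" & report$target != "pooled", ], 6)
#>  target feature_kind algorithm partition   AUC    SE SP     Q   MCC  n
#>     T01        MACCS        RF      test 0.987 0.933  1 0.967 0.935 30
#>     T01        ECFP6        RF      test 0.978 0.933  1 0.967 0.935 30
#>     T02        MACCS        RF      test 1.000 1.000  1 1.000 1.000 29
#>     T02        ECFP6        RF      test 1.000 1.000  1 1.000 1.000 29
#>     T03        MACCS        RF      test 0.969 0.933  1 0.967 0.935 30
#>     T03        ECFP6        RF      test 0.956 0.933  1 0.967 0.935 30

held <- heldout_votes(suite)
sw <- sweep_cutoffs(held$vote_count, held$label)
sw[c(1, 5, 9, 13, 16), ]
#>  cutoff   AUC     Q     SE SP   MCC
#>       1 0.500 0.506 1.0000  0 0.000
#>       5 0.978 0.978 0.9556  1 0.956
#>       9 0.978 0.978 0.9556  1 0.956
#>      13 0.944 0.944 0.8889  1 0.893
#>      16 0.544 0.539 0.0889  1 0.215

v <- collect_votes(suite, bm$targets[[1]]$signature[1], "T01")
v$vote_count           # 14 of 16 classifiers vote positive
call_interaction(v)    # "active" at the default cutoff of 9
```

Reading the sweep: at cutoff 1 a single optimistic classifier suffices,
so every pair is called active (SE = 1, SP = 0); at cutoff 16 unanimity
is required and sensitivity collapses (SE = 0.09). Accuracy peaks on a
plateau of interior cutoffs — the behaviour the default cutoff of 9
exploits. The held-out RF rows show the per-target models recovering the
planted structure–activity signal (AUC 0.96–1.00).

## Command line

A thin CLI over the same functions lives in `exec/mtqsar`:

```sh
mtqsar simulate --targets 5 --compounds 400 --seed 1 --out data/
mtqsar train    --activities data/activities.csv --fasta data/targets.fasta --seed 1 --out suite/
mtqsar evaluate --suite suite/ --partitions test,cv --out evaluation.csv
mtqsar sweep    --suite suite/ --out sweep.csv
mtqsar predict  --suite suite/ --molecules query.smi --cutoff 9 --out predictions.csv
mtqsar network  --predictions predictions.csv --filter-median --out network
mtqsar pipeline --config run.yaml
```

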
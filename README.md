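# isosig — transcript isoform signatures of tumor stage and survival

Bulk RNA-seq quantifies not only how much a gene is expressed but which of
its transcript isoforms carry that expression. `isosig` builds predictive
signatures of tumor progression from the *relative* abundance of isoforms —
the percent spliced in,

PSI(t, s) = TPM(t, s) / Σ_{t' ∈ gene(t)} TPM(t', s) ∈ [0, 1],

where a gene is a set of transcripts that overlap on the same strand and
share at least one splice site, and genes below 0.1 TPM in a sample
contribute missing PSIs rather than noise. The package is aimed at
computational cancer-genomics groups who have a transcript × sample TPM
matrix, a GTF annotation, and a clinical table (TNM/S stage, survival) and
want stage- or survival-linked isoform signatures with honest validation.

The core procedure:

1. **Effect gate.** Only features with |ΔPSI| ≥ 0.1 between the compared
   groups (or a log₂ fold-change gate for gene-level features) enter
   selection.
2. **Permutation-calibrated selection.** Over 100 balanced subsampling
   iterations (equal numbers drawn from each group, per tumor type for
   pooled designs), each candidate is discretized (Fayyad–Irani MDLP) and
   scored with three entropy measures against the group label S:
   IG(S,A) = H(S) − H(S|A), GR(S,A) = IG/H(A), SU(S,A) = 2·IG/(H(S)+H(A)).
   Each iteration also permutes the drawn labels and rescores; a feature is
   *discriminant* when its mean observed value exceeds its mean permuted
   value for all three measures.
3. **Redundancy removal.** Correlation feature selection (CFS) maximizes
   merit(F) = k·r̄_cf / sqrt(k + k(k−1)·r̄_ff) with symmetrical-uncertainty
   correlations, keeping discriminating power while dropping redundant
   isoforms.
4. **Classifier.** A logistic model tree (information-gain splits,
   LogitBoost simple-logistic leaves, internal cross-validation for the
   boosting count and the depth/pruning), evaluated by stratified ten-fold
   cross-validation with AUC and precision–recall area.
5. **Validation.** Cancer-hallmark Fisher enrichment with BH correction,
   Wilcoxon differential expression, Kaplan–Meier / Cox survival
   comparison, and a *blind test*: samples lacking the stage label are
   predicted with their tumor type's model and the predicted-early versus
   predicted-late pools are compared on survival.

A fully seeded synthetic-cohort generator (`simulate_cohort()`) with
planted isoform switches, expression changes, and survival effects makes
every stage testable without external data.

## Worked example

```r
library(isosig)

co       <- simulate_cohort(cohort_spec(n_genes = 100, n_planted_psi = 5,
                                        delta_psi = 0.4, seed = 7))
design   <- cohort_design(co)                      # M0 vs M1, 50 vs 50
grouping <- build_gene_groups(co$annotation)
psi      <- compute_psi(co$tx, grouping)
eff      <- effect_sizes(psi, design)
stats    <- subsample_selection(psi, design, eff, selection_config(seed = 7))
sig      <- train_signature(psi, design, stats, lmt_config(boost_iter = 50, seed = 7))
print(sig)
print(sig$cv)
```

prints

```
signature for class 'M': 1 features (CFS merit 1.000), mean CV AUC 0.999
cross-validation over 100 folds: AUC 0.999 [0.900, 1.000], PRC 0.999 [0.900, 1.000]
```

The five planted isoform switches (ΔPSI = 0.4) all pass the effect gate and
the permutation calibration (13 discriminant isoforms: the planted
transcripts plus their renormalized siblings); CFS collapses them to a
single non-redundant feature whose logistic model tree separates the
groups almost perfectly in held-out folds. On the same cohort,

```r
lab <- co$truth$true_labels
survival_compare(co$clinical, names(lab)[lab == "early"], names(lab)[lab == "late"])
#> survival comparison: 50 vs 50 samples (73 events), HR = 1.511, Cox p = 0.0903
```

recovers the generator's hazard ratio of 2 only as a trend — at 50 + 50
samples the Wald test is underpowered, which is exactly why the blind-test
stage pools predictions across tumor types before testing survival.

A thin command-line front end over the same functions ships in
`inst/cli/isosig.R` (`simulate`, `quantify`, `select`, `train`,
`survival`, `enrich`, `blindtest`, `subgroup`).

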
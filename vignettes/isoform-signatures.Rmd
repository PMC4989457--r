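---
title: "Isoform signatures of tumor stage: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform signatures of tumor stage: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isosig)
```

## The model

`isosig` treats tumor progression as a two-group classification problem on
transcript *relative* abundances. For a transcript $t$ in sample $s$,

$$\mathrm{PSI}(t,s) = \frac{\mathrm{TPM}(t,s)}{\sum_{t' \in g(t)} \mathrm{TPM}(t',s)},$$

where the gene $g(t)$ is defined structurally: transcripts that overlap on
the same chromosome and strand and share at least one splice-site
coordinate are merged, transitively, into one gene (`build_gene_groups()`).
This definition is annotation-driven rather than identifier-driven, so it
works on any GTF, and it guarantees that PSIs of a gene's transcripts sum
to one wherever the gene is expressed. Genes below 0.1 TPM in a sample are
treated as *unobserved* there — their transcripts get missing PSIs, never
zeros — because a ratio with a near-zero denominator measures noise, not
splicing.

The comparison design is always two named groups: early versus late stage
for a TNM/S class (the packaged `stage_groupings()` table records which
labels are pooled per cohort, as data rather than code), marker-gene
expression extremes (`rank_subgroups()`, e.g. estrogen-receptor or MITF
top/bottom quantiles), or survival-time extremes (`survival_groups()`).

### Feature selection

Selection is deliberately conservative, combining an effect-size gate with
a permutation-calibrated dependence test:

* **Gate.** A transcript enters scoring only if its full-cohort group-mean
  PSI difference satisfies $|\Delta \mathrm{PSI}| \ge 0.1$ (gene features:
  $|\log_2$ fold change$| \ge 2$ with a 0.01 TPM pseudo-count), and only if
  it is observed in at least 80 % of the samples of each group. There is no
  imputation at this stage: imputing PSI would fabricate exactly the signal
  being tested.
* **Balanced subsampling.** Clinical stage groups are very unbalanced
  (often 10:1). Each of 100 iterations draws the same number of samples
  from each group — the minority group size, per tumor type in pooled
  designs — so the entropy of the label margin is constant by construction
  and the information measures are comparable across features and
  iterations.
* **Scoring.** Within each draw, each candidate is discretized with
  supervised Fayyad–Irani MDLP (median-cut fallback when MDLP accepts no
  cut, so every non-constant feature keeps a total two-bin mapping) and
  scored with information gain, gain ratio, and symmetrical uncertainty in
  bits. The same draw is rescored once with the drawn labels permuted
  uniformly at random; permuting within the balanced subset keeps the
  null's label margin identical to the observed one.
* **Decision.** A feature is *discriminant* iff it passes the gate and its
  mean observed value exceeds its mean permuted value for all three
  measures. The three measures weight the feature's bin structure
  differently (GR and SU penalize many-binned features), so requiring all
  three suppresses discretization artifacts.

The redundancy step is classic CFS: maximize
$\mathrm{merit}(F) = k\,\bar r_{cf} / \sqrt{k + k(k-1)\,\bar r_{ff}}$ with
symmetrical-uncertainty correlations computed on the full comparison
cohort (subsample-level correlations would be noisy and make the selected
set unstable). Instances with at most 12 candidates are solved by
exhaustive subset enumeration — at that size exactness is cheaper than
heuristics — and larger instances by best-first search with a stall limit
of 5 non-improving expansions.

### The classifier

The signature model is a logistic model tree: a small tree grown by
information-gain splits whose leaves carry additive logistic functions
built by LogitBoost with one-variable weighted least-squares base learners
(working responses clipped at $|z| \le 3$). Two choices are made by
internal 5-fold cross-validation on the training data only: the boosting
iteration count, chosen once at the root and reused at every leaf, and the
tree depth (0 … `max_depth`), which is the pruning mechanism — a subtree
that does not reduce cross-validated error is never grown. Depth 0 is the
degenerate case, a single boosted logistic regression. This is a
simplified but faithful LMT: the procedure (tree + boosted logistic
leaves + CV-based stopping and pruning) is preserved; bit-compatibility
with any particular implementation is not promised.

Accuracy is estimated by stratified ten-fold cross-validation, repeated
(10 repeats in the test suite, 100 in production runs — both are a
configuration field, `lmt_config(repeats = )`). AUC uses the Mann–Whitney
rank formulation with tied scores counting half; the precision–recall
area uses step-wise (achievable) interpolation, which avoids the
optimistic bias of trapezoids in PR space. Missing feature values are
median-imputed from the training folds only. Cross-validation
canonicalizes samples by name before folding, so results depend on data
and seed but not on input order.

### Downstream validation

* **Hallmark enrichment** (`fisher_enrichment()`): two-sided Fisher exact
  tests against an explicit background — expressed, multi-transcript genes
  — with Benjamini–Hochberg correction at FDR < 0.05.
* **Differential expression** (`differential_expression()`): Wilcoxon
  rank-sum per gene with $|\log_2 FC| > 0.5$ and adjusted $p < 0.05$; a
  signature whose genes show no DE carries information beyond expression.
* **Survival** (`survival_compare()`): Kaplan–Meier curves and a single
  binary-covariate Cox proportional-hazards fit (Efron ties; Wald $p$),
  via the `survival` package.
* **Blind test** (`blind_test()`): samples lacking the stage label — never
  seen during training — are predicted with their own tumor type's model
  at a 0.5 probability threshold, restricted to tumor types whose labeled
  groups already separate on survival (Cox $p < 0.05$); predicted pools
  are aggregated across types before the survival comparison. This is the
  package's external-validation surrogate: a signature that merely
  memorizes its cohort will not separate survival on samples it has never
  labeled.
* **Purity screen** (`geneset_sample_score()` +
  `correlate_psi_scores()`): per-sample stromal/immune scores are the mean
  over set genes of within-cohort rank z-scores — a deliberately simple,
  monotone-invariant summary, *not* GSVA's kernel estimator, and named
  accordingly in outputs. Downstream use is only Pearson-correlation
  screening of model PSIs, which is robust to the scoring flavor.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_gene_tpm` | 0.1 | TPM | below this, PSI denominators are noise |
| `effect_threshold` | 0.1 (PSI), 2 (log₂ gene) | PSI / log₂ | minimum biologically meaningful shift |
| `n_iterations` | 100 | draws | stabilizes observed/permuted means |
| `min_group` | 10 | samples | below this a balanced draw is uninformative |
| `min_present` | 0.8 | fraction | missingness ceiling per group, no imputation |
| `epsilon` | 0.01 | TPM | pseudo-count for fold changes |
| `boost_iter` | 200 | iterations | LogitBoost cap; CV picks the count actually used |
| `min_split` | 15 | samples | smallest admissible child node |
| `max_depth` | 2 | levels | trees stay interpretable; CV may still pick 0 |
| `folds` × `repeats` | 10 × 10 | — | 10 × 100 for production runs |
| `psi_concentration` | 20 | — | generator PSI noise, ≈0.1 SD at PSI 0.3 |

## The synthetic cohorts

`simulate_cohort()` draws gene TPMs log-normally (baseline meanlog 2,
sdlog 1 across genes; within-gene sample noise sdlog 0.5 — TPMs mostly
1–100, as in bulk tumor data), isoform proportions from a Dirichlet around
per-gene baselines (concentration 20), survival times exponentially with a
group hazard ratio, independent exponential censoring, and blanks a
fraction of stage labels. Planted isoform switches shift the planted
transcript's late-group baseline on the logit scale so the realized mean
ΔPSI matches the requested value; sibling isoforms are renormalized.
Because PSI sums to one within a gene, those siblings *also* shift —
ground truth therefore records both the planted transcripts and the full
set of generatively shifted transcripts, and recovery metrics count a
flagged sibling as a true discovery of the same switch, not a false
positive.

The default spec — two groups of 50, 340 genes × 3 isoforms (~1000
features), 20 planted switches of ΔPSI 0.3 — is the standard condition
exercised by the test suite. The blind-test simulations use two tumor
types of 150 + 150 samples with 30 % blanked labels (a blind pool of ~90),
matching the scale at which pooled survival validation is actually
performed on real cohorts; smaller pools leave the Cox comparison
underpowered regardless of model quality.

What the generator does **not** emulate: batch effects, tumor purity
gradients, library-size artifacts, correlated gene modules, non-proportional
hazards, and informative censoring. Passing tests therefore demonstrate
that the machinery is correct and calibrated under its own assumptions —
not that real cohorts satisfy those assumptions.

## Numerical choices and degenerate inputs

* Entropies are base-2 plug-in estimates; IG is clamped at 0 against
  floating-point negatives; GR := 0 when H(A) = 0, SU := 0 when both
  entropies vanish — a constant feature scores zero on all measures.
* Quantile-based splits use `floor(n · fraction)` and break ties by sample
  id (logged), so subgroup construction is deterministic.
* MDLP cut points are midpoints between adjacent distinct values; the
  acceptance rule is the standard MDL criterion
  $\mathrm{Gain} > (\log_2(N{-}1) + \Delta)/N$.
* Per-iteration RNG streams derive deterministically from the master seed
  (`seed + 1000003·i`, kept within 32-bit range), so every run is
  bit-reproducible from its configuration.
* A zero-MAD gene yields all-zero robust z-scores; a zero-variance PSI
  yields NA correlation; an all-censored comparison errors with
  "no events" rather than returning a meaningless fit.
* Clinical readers reject duplicated sample rows outright — guessing which
  of two contradictory clinical records is right is not the package's job.

## Open design points, resolved

* The discretization used by the original univariate screen is not fully
  specified in the literature it follows; supervised MDLP is the default
  here, with `equal_frequency` (k = 3) available so the choice is
  auditable in any result.
* Whether the ΔPSI gate uses full-cohort or subsample means is ambiguous;
  full-cohort means are used (they are what "on average changes by more
  than 0.1" describes, and they make the gate deterministic).
* The subsample size per draw is the minority group size (per type in
  pooled designs): the larger group is subsampled, the smaller exhausted.
* Mean CV accuracy is the mean over all fold-level values, not over
  repeat-level means.
* The early/late label pools per cohort ship as an editable configuration
  table, not as code.

## Limitations

Transcript-level TPMs are taken as given; quantification uncertainty
(which is substantial for isoforms sharing most of their sequence) is not
propagated. Selection is strictly two-group; ordinal stage structure is
not modeled. The Cox comparison is univariate by design — it asks whether
the predicted grouping separates survival, not whether it does so
independently of age, grade, or treatment. And the test-suite problem
sizes (hundreds of samples, ~10³ features) are chosen to keep a full run
in minutes on one CPU; production-scale inputs (10⁴–10⁵ features) run the
same code paths, only longer.
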
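# immunoscreen

Case-control analysis of high-dimensional immune population frequency
tables.

`immunoscreen` is an R package for systems-immunology case-control
studies — for example a memory-clinic cohort of Alzheimer's patients and
healthy spousal controls — that start from a subjects × populations table
of flow-cytometry *percent-of-parent* frequencies plus clinical metadata
(group, age, sex, spouse linkage, MMSE band, APOE ε4 carrier status,
EBV/CMV serostatus, fluid biomarkers). It is aimed at analysts who have
already gated their cytometry data and need a reproducible, tested route
from the frequency table to disease-association statistics.

## What it computes

Given a cohort table **X** (subjects × variables) and metadata, the
pipeline runs, in order:

1. **Preprocessing** — variables with missing fraction > 20 % are
   dropped; each remaining variable is Box-Cox transformed
   (λ estimated by profile log-likelihood on [−5, 5], with
   `y = log(x + s)` at λ = 0 and shift `s = 1 − min(x)` when
   `min(x) ≤ 0`), z-scored, and missing cells imputed by k-nearest
   neighbours (Euclidean partial distance, k = 3, median aggregate).
2. **Association screen** — per variable, logistic regression
   `logit P(case) = β₀ + β₁ xᵥ + β₂ age + β₃ sex`, reporting
   OR = exp(β₁) with Wald 95 % CI and p, plus Benjamini–Hochberg
   adjusted p; and linear age models `xᵥ ~ z(age) + sex` fit separately
   in cases and controls.
3. **Model selection** — L2-penalised logistic models built incrementally
   on the top-N ranked variables (N = 1…200), age and sex unpenalised,
   scored by stratified 10-fold cross-validated AUC
   (Mann–Whitney concordance); N\* is the smallest argmax of the mean
   curve. An honest nested mode re-ranks variables inside each training
   fold.
4. **Random forest** — maximum depth tuned per fold by out-of-bag score,
   Gini impurity-decrease importance ranking, and an incremental top-N
   CV-AUC curve.
5. **Similarity** — PCA of the standardized table (equivalent to
   principal coordinates of Euclidean distances), with case-control
   separation statistics and biplot marker arrows.
6. **Spousal shared environment** — Euclidean distance between actual
   spousal pairs versus re-pairings randomized within sex-composition and
   age-bin constraints; permutation p = fraction of simulated sets whose
   median distance is ≤ the actual median; per-variable concordance
   p-value scatter against the null line.
7. **Clinical structure** — Mann–Whitney / Kruskal–Wallis comparisons
   within serology strata, disease × serostatus interaction models,
   Jonckheere–Terpstra ordered trend over MMSE severity bands, Spearman
   biomarker correlations, and Fisher-z deviation of pairwise
   correlations between groups.

A first-class synthetic cohort generator (`synthetic_truth()`,
`generate_cohort()`) plants known effect sizes, MMSE-graded severity,
spousal shared-environment correlation, age/sex structure and
baseline-dependent missingness, and exports the ground truth as JSON, so
every stage is validated by parameter-recovery tests.

## Worked example

```r
library(immunoscreen)

# A synthetic memory-clinic cohort: 120 AD patients, 90 spousal controls,
# 120 immune variables; four planted disease effects, shared household
# environment on twenty variables, 5% missingness.
vars <- synth_var_names(120)
truth <- synthetic_truth(
  120,
  effect_sizes = setNames(c(-0.9, -0.8, -0.7, 0.7), vars[1:4]),
  shared_env_variables = vars[5:24], shared_env_rho = 0.4,
  missingness_base_rate = 0.05, seed = 42
)
cohort <- generate_cohort(120, 90, truth, n_pairs = 80)
write_cohort(cohort$table, cohort$meta, "frequencies.csv", "metadata.csv")

config <- run_config(n_folds = 10, max_features = 20, rf_trees = 200,
                     n_simulated_pairings = 200, master_seed = 7)
summary <- run_pipeline(config, "frequencies.csv", "metadata.csv", "results")
```

Output of the summary lines (this exact run):

```
variables kept after >20% missingness filter: 120 of 120
optimal model size: 10 variables (CV AUC 0.868)
random forest: depth 5, peak CV AUC 0.869 at 15 variables
PCA separation (all vs top variables): 0.47 vs 1.55
spousal concordance: permutation p = 0.005 (all variables), 0.254 (disease-associated)
```

Reading the numbers: the ridge-logistic screen discriminates cases from
controls well above chance (CV AUC 0.87); the PCA embedding separates
the groups only once restricted to the top-ranked variables (0.47 → 1.55
standardized units), i.e. the disease signature is a discrete
dysregulation, not a global shift; and the spousal permutation test
detects the planted shared-household correlation across all variables
(p = 0.005) but finds none on the disease-associated subset (p = 0.25) —
the disease signal is independent of shared environment. Per-stage TSV
tables and a JSON run summary (carrying the configuration hash and all
stage seeds) are written to `results/`; the same inputs, configuration
and seed reproduce byte-identical outputs.

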
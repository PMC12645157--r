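---
title: "Methods: case-control screening of immune frequency tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control screening of immune frequency tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures implemented in
`immunoscreen`, the assumptions behind them, the tunable parameters, and
the design decisions taken where several defensible choices existed. The
package analyses case-control immunophenotyping cohorts: a subjects ×
populations table of percent-of-parent gated frequencies (0–100, missing
allowed) plus clinical metadata, with the prototypical application being
a dementia memory-clinic cohort with healthy spousal controls.

## Preprocessing

**Missingness filter.** Low-frequency populations produce unreliable
child-gate frequencies, so missingness concentrates in rare subsets. A
variable is retained iff its missing fraction is ≤ the threshold
(default 0.20); strictly greater is dropped. The boundary is inclusive:
with 5 subjects, one missing cell (20 %) survives, two (40 %) do not.
Subjects are never dropped here. Whether the filter should run before or
after any subject exclusions is not dictated by the data model; the
pipeline filters on the full subject set.

**Box-Cox + z-scoring.** Frequencies are right-skewed. Per variable the
package maximises the Box-Cox profile log-likelihood

$$\ell(\lambda) = -\tfrac{n}{2}\log \hat\sigma^2_\lambda + (\lambda - 1)\sum_i \log x_i$$

over λ ∈ [−5, 5] with `stats::optimize()` (tolerance 1e-6), snapping to a
bound when the boundary log-likelihood is at least the interior optimum.
At λ = 0 the natural log is used. Because a *subtractive* unit shift
cannot make values positive, the positivity shift is defined as
`s = 1 − min(x)` when `min(x) ≤ 0` and 0 otherwise — the smallest unit
shift guaranteeing strict positivity — and recorded per variable in the
`TransformSpec` so the fit can be reapplied to new data. Transformed
variables are z-scored with the pooled mean and SD over *all* subjects
(cases and controls together); per-group standardisation would absorb
the group effect being tested. Variables with fewer than 10 observed
values or zero variance are dropped with a warning. All these transforms
are monotone, so within-variable ranks of observed cells are invariant —
a property the test suite asserts.

**kNN imputation.** Each missing cell is replaced by the median (mean
configurable) of the variable's values in the k = 3 nearest subjects.
Distance between two subjects is the squared-difference mean over the
variables observed in *both*, rescaled by the total variable count
(standard partial-distance scaling); subjects sharing no observed
variable are an error. Ties in donor distance are broken by subject-id
order so imputation is deterministic. The median aggregate is robust to
a single aberrant donor, which matters because donors are selected on a
partial distance. Imputation requires a standardized table (a
raw-percent table would let high-frequency populations dominate the
distance); the function refuses input whose column means are far from 0
unless overridden.

## Association screen

Per variable, disease status is modelled by maximum-likelihood logistic
regression on the (standardized) variable with age and sex as
covariates; the report contains OR = exp(β), Wald 95 % CI and p. Wald
rather than profile-likelihood intervals are used because ORs and CIs
are reported symmetrically on the log scale and the per-variable screen
must be cheap at hundreds of variables. Sex is coded as a single M
indicator (reference F, alphabetical); the coefficient of interest is
the variable's, which is unaffected by the reference choice.
(Quasi-)complete separation and non-convergence are detected (glm
warnings, |β| > 15 or SE > 10 on a standardized variable) and the record
is *flagged unusable* rather than reported as a silently extreme OR.
Age associations are ordinary least squares of the variable on z-scored
age and sex, fit separately within cases, controls, or all subjects.

Variables are ranked by raw p (ties by |log OR| descending, then name;
flagged records last). Benjamini–Hochberg adjusted p-values are computed
across the screen and carried alongside raw p — ranking uses raw p, the
stratified group comparisons use BH within their own family.

## Incremental penalised models and cross-validated AUC

For N = 1…`max_features` an L2-penalised logistic model is fitted on the
top-N ranked variables plus *unpenalised* age and sex (they are
adjustments, not candidate markers), inside each of k = 10 stratified
folds, and the held-out fold is scored. AUC is the Mann–Whitney
concordance `(concordant + 0.5·ties) / (n₁n₀)`; the curve reports the
across-fold mean with a t-interval. N\* is the smallest N attaining the
maximal mean AUC.

Two numerical choices deserve note:

* **Penalty scale.** The ridge penalty is parameterised on the classical
  penalised-likelihood scale, `−ℓ(β) + (λ/2)‖β‖²` with λ = 1.0 by
  default; the `glmnet` backend receives `λ/n_train`. A single fixed λ
  keeps the N-sweep interpretable; sensitivity can be explored through
  the configuration.
* **Ranking leakage.** With the default *full-data* ranking, the top
  variables were selected using all subjects, including each held-out
  fold, so the curve inherits selection optimism: on synthetic data with
  4 real effects among 200 nulls the curve keeps creeping upward past
  the true model size. The package therefore also provides an honest
  *nested* mode (`nested = TRUE`) that recomputes the univariate ranking
  inside every training fold; on the same synthetic data the nested
  curve rises to N = 4 and then declines, which is the behaviour the
  validation suite asserts. The default remains the full-data ranking
  because it is the cheaper, literal screen; any peak-location claim
  should use the nested mode.

The averaged ROC curve evaluates each fold's ROC as a step function on a
fixed false-positive-rate grid (step 0.01), averages vertically, and
draws a normal-approximation band from the across-fold SD.

## Random forest

Maximum tree depth is the one regularisation knob: for each stratified
fold, forests are grown at every depth in the grid (default
{2, 3, 4, 5, 7, 10, unlimited}; unlimited is encoded as 0 and ordered
last) on the training part, the per-fold best depth is the smallest
maximising the OOB accuracy, and the final depth is the mode of the
per-fold choices (smallest on multimodality). A final 500-tree forest on
the full data yields Gini impurity-decrease importances, normalised to
sum 1 and ranked descending with a name tie-break. 500 trees is chosen
for importance stability, not accuracy. Incremental top-N curves reuse
the same stratified-CV AUC machinery as the penalised models; all forest
fits are single-threaded with derived seeds, so results are exactly
reproducible. Correlated duplicates share importance (each copy may
halve while their sum is preserved) — a documented masking property of
impurity importances, asserted in the tests.

## Similarity embedding

The PCA embedding operates on the column-standardized table; classical
multidimensional scaling of the Euclidean distance matrix is identical
(up to sign) for such input, which resolves the ambiguity between "PCA
on the data" and "PCA on distances" — the equivalence is asserted
numerically in the test suite. Signs follow a deterministic convention
(the largest-|loading| variable is positive on each component). Group
separation per component is the standardized mean difference; the
overall statistic is the Euclidean norm over the first two components,
invariant to sign flips. On synthetic cohorts with a small planted
signature, the embedding of *all* variables separates groups poorly
while the embedding of the top-ranked subset separates them clearly —
the qualitative pattern expected when disease perturbs a few populations
out of hundreds.

## Spousal shared-environment analysis

Cohabiting spouses share diet, pathogen exposure and lifestyle, so their
immune profiles are more similar than random pairs of the same age/sex
structure. The package quantifies this as the per-pair Euclidean
distance over selected variables, compared with *constraint-preserving*
re-pairings:

* partners are permuted only within strata of identical (partner sex,
  partner age bin), with 10-year bins by default, so the multiset of
  pair sex compositions is preserved exactly and the within-pair age-gap
  distribution approximately;
* within a stratum a derangement is attempted (up to 20 redraws) so
  simulated pairs avoid reproducing actual couples; singleton strata
  make some repeats unavoidable and their count is recorded per set;
* the permutation p-value is `(1 + #{sets: median ≤ actual median}) /
  (1 + n_sets)`, one-sided toward concordance, with 1000 sets by
  default.

For the per-variable concordance scatter, partner order within each pair
is arbitrary; it is randomized once per pair (seeded) and reused across
actual and simulated sets so ordering artefacts cancel. Each variable's
actual Spearman rank-correlation test p is plotted against the
geometric mean (Fisher-combined, back-transformed) of the same statistic
over simulated sets; the identity line is the no-shared-environment
null, and a least-squares fit of −log₁₀ p summarises the deviation.
Restricting the distance analysis to disease-associated variables that
carry no shared-environment loading removes the concordance signal — the
synthetic analogue of showing that a disease signature is
environment-independent.

## Clinical-structure tests

Nonparametric comparisons deliberately mirror standard practice:
Mann–Whitney U (exact for combined n ≤ 12 without ties, tie-corrected
normal approximation otherwise), Kruskal–Wallis with tie correction
followed by pairwise Mann–Whitney with BH adjustment *within the
variable*, and a linear disease × stratum interaction model with age and
sex covariates. Severity trends across ordered groups (healthy controls,
then MMSE bands 25–30, 20–24, 10–19, <10) use the Jonckheere–Terpstra
statistic — ascending cross-group pairs, ties half-weighted — with an
exhaustive-enumeration exact p for total n ≤ 10 and a tie-corrected
normal approximation with continuity correction otherwise. The exact
cutoffs (12 and 10) keep the enumerations instantaneous while covering
the hand-checkable cases. Group-correlation deviations use the Fisher z
difference `(atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3))` with BH across
pairs; |r| = 1 is an error rather than an infinite z. BH families are
never pooled across unrelated analyses; every stratified rerun records
its subset filter expression in the output.

## The synthetic cohort generator

`generate_cohort()` is the package's test bed and defines the conditions
under which the pipeline is validated. Per subject and variable a
Gaussian latent is built as

```
latent = age_slope · z(age) + sex_effect · 1(male)
       + effect · severity_mult · 1(case)
       + sqrt(rho) · pair_shared + sqrt(1 − rho) · noise
```

and mapped to percent-of-parent scale by
`freq = min(100, baseline · exp(scale · latent))` with baselines
log-uniform on 0.01–31.6 % and log-scales uniform on 0.3–0.6. Effects
are planted on the latent scale precisely so that Box-Cox + z-scoring
approximately recovers them, making parameter-recovery tests analytic
(Box-Cox λ is then ≈ 0 and the transform is affine in the latent).
Severity multipliers follow a monotone ladder over MMSE bands
(0.4 / 0.7 / 1.0 / 1.3 from mild to severe), normalised by their
expectation under the band mix so that `effect_sizes` remain *marginal*
standardized AD−HC differences; without the normalisation every planted
effect would be attenuated by the mean multiplier and moment-recovery
checks would drift. Ages are truncated-normal (mean 70, SD 9) on a
configurable 45–83 range, identical for both groups; spouses get the
partner's age ± N(0, 3) and the opposite sex, emulating spousal
age-matching. Missingness is missing-at-random given the variable's
baseline: per-variable probability decreases linearly in the baseline
rank with mean equal to the configured base rate (default 0.05),
mimicking the difficulty of gating children of rare populations.

What the generator does **not** emulate: the gating hierarchy's
sum-to-parent constraints and the resulting correlation structure
between parent and child populations, batch effects, heavy-tailed
technical outliers, informative missingness (missing because the value
itself is extreme), and comorbidity/medication structure. Passing
recovery tests therefore demonstrates that the statistical machinery is
correct under its stated model, not that real cytometry data meet that
model.

## Determinism and problem sizes

One master seed expands into fixed per-stage seeds
(`stage_seed(master, stage)` = master·100 + a documented offset), every
stochastic routine takes an explicit seed, forests run single-threaded,
and RNG state is always restored (`with_seed()`), so a pipeline rerun
with identical inputs and configuration is byte-identical — asserted on
the JSON summary and every stage output. The validation suite sizes its
simulations for deterministic, minute-scale runs on one core: 20 seeds ×
(300 + 300 subjects × 204 variables) for ranking/peak recovery, 500 + 500
subjects for the theoretical-AUC check, 200 null runs of 150 spousal
pairs × 30 variables (99 re-pairings each) for permutation calibration,
20 seeds of 200 × 50 matrices for the imputation benchmark, and 200
seeds per test family for null-calibration KS checks. These sizes are
the package's validation conditions; nothing in the methods depends on
them.

## Known limitations

* The pipeline is cross-sectional: no longitudinal or mixed models.
* Transform and imputation statistics are fitted once on the full table
  before cross-validation; the CV curves therefore share a small amount
  of preprocessing information across folds. The nested mode removes
  ranking leakage but not preprocessing leakage, which is the standard
  simplification in this analysis family.
* With realistic gating panels (thousands of gated populations filtered
  down to several hundred analysable variables), the retained variable
  count is data-dependent; the pipeline records realised counts per run
  rather than assuming them.
* Impurity importances are biased toward variables with many split
  points and split among correlated variables; they are used for
  *ranking*, not effect estimation.
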
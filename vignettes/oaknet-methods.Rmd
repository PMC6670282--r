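---
title: "Semihandcrafted Bayesian networks for knee-OA prescreening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semihandcrafted Bayesian networks for knee-OA prescreening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oaknet)
```

## The problem and the model

Knee osteoarthritis (OA) in older adults is usually confirmed by imaging,
which is expensive, immobile and unsuitable for some patients. A cheap
prescreening alternative is to score the *risk* of knee OA from measurements
any community health worker can collect: five background characteristics
(gender, age, education, body-mass index, waist-to-hip ratio) and six
physical-fitness tests, one of which — the Star Excursion Balance Test
(SEBT) — contributes eight normalized reach directions, for thirteen
predictor attributes in total.

`oaknet` models the 19 variables (18 attributes plus the OA label) as a
discrete Bayesian network with a fixed *three-level* shape: every background
node is a parent of the disease node, and the disease node is a parent of
every predictor. This handcrafted star (18 edges, the "HBN") encodes the
clinical reading — backgrounds are risk factors, fitness scores are
consequences of disease status. Because the handcrafted shape cannot express
correlations *between* predictors (the eight SEBT directions are reaches of
the same test and are strongly correlated), the structure is then *retrained*:
a constrained greedy search adds, deletes or reverses predictor–predictor
edges, scoring each candidate by 5-fold cross-validated classification
accuracy. The refined network is the semihandcrafted model ("SHBN").

Inference is exact. The posterior
$P(\text{OA} \mid \text{evidence})$ is computed by variable elimination with
a min-fill ordering; a brute-force enumeration engine over the full joint
table serves as an independent oracle, and their agreement (within $10^{-10}$)
is asserted in the test suite rather than assumed. A record is called
positive when the posterior reaches the decision threshold (default 0.5);
ties are called positive because, for a prescreening tool, the missed case
is the costlier error. Any subset of the 18 attributes may serve as
evidence, so prediction degrades gracefully when a subject cannot complete
a test.

## The pipeline

The preprocessing chain mirrors the epidemiological workflow end to end:

1. **Derivation** — BMI = weight/height², WHR = waist/hip replace the four
   raw anthropometric columns.
2. **Filtering** — records missing more than 6 of the 18 analysis
   attributes are dropped (`filter_incomplete()`); beyond a third missing,
   a record carries too little information to impute.
3. **Imputation** — column means for continuous attributes, column modes
   for categorical ones, ties toward the lower state
   (`impute_missing()`). Imputed cells are flagged.
4. **Balancing** — SMOTE oversampling of the positive class on the
   continuous scale (`smote_oversample()`): each synthetic record
   interpolates a random minority record toward one of its 5 nearest
   minority neighbours (Euclidean distance on standardized continuous
   attributes; categoricals copied from the seed record). The default of
   26 synthetic records reproduces the reference bookkeeping, 53 + 26
   positives against 78 negatives = 157 records, 50.3% positive.
5. **Discretization** — every continuous attribute is cut into two states.
   Cutpoints are learned by *exact* one-dimensional k-means
   (`learn_cutpoint_kmeans()`): optimal 1-D clusters are contiguous in
   sorted order, so dynamic programming over split positions finds the
   global within-cluster-SS optimum deterministically, with the cutpoint at
   the midpoint of adjacent cluster means. The package also ships the
   published cutpoint set verbatim (`table3_scheme()`), including its
   inconsistent boundary conventions (the cutpoint itself belongs to the
   lower state everywhere except BMI, where 25 kg/m² opens the upper
   state); the `discretization_scheme` type makes the convention explicit
   per attribute rather than hiding it.
6. **Split and evaluation** — a stratified 30% of the final dataset trains
   the structure; the remaining 70% is scored by stratified 5-fold
   cross-validation, fitting conditional probability tables (CPTs) on each
   training fold.

Ordering choices the workflow fixes (and exposes in configuration):
imputation runs on the post-filter records, before SMOTE and before
discretization; SMOTE runs on the whole dataset before the
structure/evaluation split, which reproduces the original protocol
faithfully even though it lets synthetic neighbours leak across folds —
a caveat worth knowing, not silently "fixing". Cutpoints are learned on the
final balanced dataset by default.

## Parameter learning

CPTs are estimated by expectation–maximization (`em_fit()`). The E-step
(`expected_counts()`) computes, for every node/parent configuration, the sum
over records of the exact posterior probability of that configuration given
the record's observed cells; records are grouped by their unique pattern of
observed values first, and the completions of the missing cells are
enumerated and weighted by their joint probability, so the step is exact.
For complete records the E-step degenerates to hard counts, and `em_fit()`
then reduces in one step to the closed-form smoothed frequency estimator
(`fit_cpts()`).

Defaults: Dirichlet pseudo-count 1 per CPT cell (at ~110 training records a
multi-parent CPT has many unobserved cells, and unsmoothed zeros poison
inference), uniform initialization (deterministic; random initialization is
available behind a seed), convergence when the observed-data log-likelihood
improves by less than `1e-4`, at most 200 iterations. With pseudo-count 0
the observed-data log-likelihood trace carries the classical EM
monotonicity guarantee, which the tests assert across 100 random
incomplete-data problems; with smoothing the maximized objective is the
posterior density, and the reported trace remains the observed-data
log-likelihood.

## Structure search

"Retraining" the structure is greedy hill climbing under explicit
constraints (`structure_constraints()`): the 18 base edges are required;
only predictor–predictor edges are mutable by default (the one edge class
where hidden relationships are clinically plausible — reaches of the same
balance test); a 4-parent cap guards CPT size at cohort-scale n (required
base parents are exempt, the disease node keeps its five background
parents). The score is the *wrapper* criterion: mean accuracy of the
disease classifier over 5 stratified folds with CPTs re-fit per fold
(`cv_accuracy_score()`). The search accepts the best strictly-improving
move; exact ties prefer fewer edges, then the lexicographically smaller
edge set, so reruns are bit-reproducible. Random restarts (default 2)
perturb the start with two random admissible edges; the best climb wins and
is never worse than the base structure's score.

Because accuracy is not decomposable over families, a naive implementation
re-fits the whole network per candidate move. The search instead caches,
per fold, each node's log-CPT contribution to the two disease-state joint
log-likelihoods of the held-out records; a move touches one node's parent
set (two for a reversal), so only that contribution is re-fit. The cached
score is the same quantity `cv_accuracy_score()` computes, and the test
suite asserts their equality move by move on a small network.

A wrapper score can only discover edges that change the disease posterior.
The structure-recovery harness (`ground_truth_shbn()`,
`structure_recovery_run()`) therefore injects three SEBT–SEBT edges whose
children are, given OA status alone, uninformative (the disease effect
flips direction with the SEBT parent's state) but strongly informative once
the edge is modelled. On cohorts of n = 2000 sampled from this generator
the search recovers the injected skeleton reliably; edges that are neutral
for classification are invisible to this score by design, which is the
honest statement of what "Bayesian-search retraining scored by CV accuracy"
can and cannot find.

## Evaluation protocol

Fold confusion matrices are pooled (micro-averaged) for accuracy,
sensitivity (true-positive rate) and specificity (true-negative rate);
out-of-fold scores are pooled for the AUC (Mann–Whitney rank form, ties
half-weighted). Macro-averaging is available behind a flag since the
original report does not say which was used. Undefined metrics (empty
denominators) raise errors rather than returning `NaN`.

Because a prescreening tool is deployed at population prevalence rather
than the balanced study prevalence, predictive values are reported via
Bayes' theorem at assumed prevalences $p \in \{1\%, 10\%, 20\%\}$:

$$\mathrm{PPV} = \frac{se\,p}{se\,p + (1-sp)(1-p)}, \qquad
  \mathrm{NPV} = \frac{sp\,(1-p)}{sp\,(1-p) + (1-se)\,p}.$$

For fixed $(se, sp)$, PPV increases and NPV decreases monotonically in $p$,
with limits 1 at the respective extremes — both verified on a grid. Applied
to the published sensitivity/specificity of each comparator model
(`reference_performance()`, ingested constants — the six standard
classifiers are deliberately not re-implemented), these formulas reproduce
all 48 published predictive-value cells after 2-decimal rounding
(`predictive_value_table()`), and `percent_gain()` reproduces the published
improvement percentages, including the convention that predictive-value
gains are computed on the rounded values.

## The synthetic cohort generator

The subject-level study data are not deposited, so the generator *is* the
study-conditions definition for every downstream test. It emulates, at
n = 131: the categorical composition by exact largest-remainder allocation
(45/86 male/female, 78/53 OA-negative/positive — 40.5% positive — and the
education split), continuous attributes matched to the published
means/SDs, and sparse missingness (education 8/131, sit-and-reach 3/131,
i.e. the 11 missing cells of 2489).

Distributional choices:

* Continuous attributes are truncated Gaussians at physical bounds (age
  60–80 years, times positive, SEBT in (0, 2]), with the underlying
  parameters calibrated so the *post-truncation* moments match the printed
  ones. Two attributes fall outside what that family can express: the
  single-leg stance time (mean 72.77 s < SD 81.84 s) and leg extension
  power are more right-skewed than the family's exponential limit, so they
  are drawn from exactly moment-matched lognormals instead. Age's printed
  SD sits at the feasibility edge of a [60, 80]-truncated Gaussian; the
  calibration weights the mean so the ~1% residual lands on the SD.
* The OA effect is a mean shift of 0.5 within-class SD on each predictor
  (slower timed-up-and-go and reaction time, shorter stance, reach, power
  for positives), with the within-class variance deflated so the marginal
  moments still match. The true class-conditional distributions are
  unpublished; 0.5 SD is a stand-in chosen to make the classification task
  learnable but imperfect, and it is configurable, not an estimate.
* Background attributes carry no disease signal in the default profile, so
  the background-only ablation calibrates near AUC 0.5 on synthetic data;
  the ablation check is therefore a direction check (full > background),
  not a reproduction of the published ablation AUC.
* The eight SEBT directions share an equicorrelated Gaussian copula
  (ρ = 0.5), mirroring correlated reaches of one test; no richer
  dependence is attempted.
* Missingness is MCAR — the reported causes (scheduling conflicts, test
  failures) are treated as ignorable.

What passing tests on this cohort do and do not show: they validate the
machinery (bookkeeping, learning, inference, evaluation) under realistic
marginals, class imbalance and sparse missingness; they cannot validate the
published real-data metrics, because the real dependence structure is
unknown. Synthetic-cohort results are labelled as such throughout.

## Numerical and design notes

* CPT rows must sum to 1 within `1e-12`; posteriors within `1e-10`.
  Zero-probability evidence raises an explicit "impossible evidence" error
  instead of returning `NaN` or a uniform.
* States are indexed from 1 in all I/O, matching the published state
  labels; XMLBIF 0.3 serialization stores the level tags as node
  properties (the format has no native slot), and a JSON dialect carries
  them natively.
* Stratified folds deal class remainders to the least-loaded folds, so
  157 records split 5-ways gives sizes 32/32/31/31/31 with class shares
  within one record of global.
* One run seed fans out to per-stage seeds (simulation, SMOTE, split,
  search, folds) by a fixed affine rule, so any stage can be rerun in
  isolation and a config hash plus seed determines every artifact byte.
* Problem sizes used by the test suite and the acceptance script —
  inference-oracle sweeps over hundreds of random small networks plus the
  19-node topology, EM recovery at n = 5000 with 10% missingness,
  structure recovery over 20 cohorts of n = 2000, direction checks over
  10–20 cohorts of n = 131 — were chosen as the smallest designs at which
  the corresponding guarantees are statistically meaningful.

## Known limitations

* No approximate inference; unnecessary at 19 nodes and deliberately out
  of scope, as are continuous/hybrid nodes.
* The wrapper score inherits the noise of 5-fold accuracy at n ≈ 47
  structure-training records; on small cohorts the search can accept
  chance edges. The published-style two-stage split keeps this honest
  (evaluation folds never see the structure-training records).
* SMOTE before the split reproduces the original protocol, including its
  leakage of synthetic neighbours across folds; fold-internal balancing
  would be the methodologically clean alternative and is not currently
  implemented.
* Mean/mode imputation understates uncertainty relative to multiple
  imputation; it is the protocol being modelled, not a recommendation.
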
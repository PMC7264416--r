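---
title: "Methods: multi-omics prognostic analysis and target regulation simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics prognostic analysis and target regulation simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Colon adenocarcinoma cohorts profiled on several molecular layers — gene
expression, exon expression, DNA methylation and somatic mutations — carry
partially complementary prognostic information. `coadmark` implements a
pipeline that (i) screens each layer for features that separate long- from
short-surviving patients, (ii) compresses each layer to a handful of
*essential features* by exploratory factor analysis (EFA), (iii) trains
binary prognosis classifiers on every combination of layers, (iv) ranks
biomarkers by an in-silico *target regulation simulation* (TRS) that asks
which feature knock-downs would flip a poor-prognosis patient's predicted
class, and (v) summarises the surviving biomarkers as a linear prognosis
risk score (PRS) with survival-analysis and protein–protein-interaction
(PPI) annotation around it.

Every stage is exercised against synthetic cohorts with planted effects,
so the whole pipeline is testable offline.

## Prognosis labels

Overall survival (OS) is dichotomised at 5 years (1,825 days): samples
surviving longer are *positive* (good prognosis), samples with an observed
death at or before the threshold are *negative*. Samples censored before
the threshold are *excluded*: their 5-year status is unknowable, and
treating them as negatives would contaminate the negative class with
patients who may well have survived. This exclusion rule is a package
decision; the alternative (censored-as-negative) can be emulated by
editing the event column upstream.

## Screening

Each feature is tested by a two-sided Welch (unequal-variance) *t*-test
between the groups, with fold change FC = mean(negative)/mean(positive).
The gates are: keep the top 1,000 features by ascending *p*, then require
*p* < 0.01 and FC > 1.5 or FC < 2/3. The FC orientation reflects the
empirical pattern that prognosis-differential features tend to be higher
in the poor-prognosis group; because the gate is symmetric the orientation
is not destructive. An epsilon guard (1e-8 × the grand mean of the layer)
keeps FC finite for sparse layers. Mutation (0/1) features run through the
same test; note that for binary features a small *p* implies a large FC,
so the FC gate does essentially no additional filtering there — a
limitation of applying one screening procedure to all four layers.

Raw *p*-values are used (no multiplicity correction), matching common
practice for this style of prefilter-plus-gate screening; the gates, not
the *p*-values, control the false-positive load.

## Factor reduction

Per layer, the differential submatrix is factor-analysed:

* **Retention** — Kaiser criterion: the number of eigenvalues of the
  feature correlation matrix strictly above 1, floored at 1. The criterion
  is deterministic and is the common default of EFA tooling.
* **Extraction** — minimum-residual (minres): uniquenesses are optimised
  by L-BFGS-B (bounds [0.005, 1], started at 1 − squared multiple
  correlations) so that the rank-k eigen-approximation of the reduced
  correlation matrix minimises the off-diagonal residual sum of squares.
  The start and optimiser are fixed, so fits are deterministic.
* **Rotation** — varimax without Kaiser row-normalisation. On fixtures
  with uneven communalities the row-normalised variant smears loadings
  across factors; the unnormalised rotation recovers planted simple
  structure cleanly and is the default of the common GPArotation engine.
* **Scores** — Thurstone regression scores, `Z R^{-1} L`.

Loadings are taken in absolute value ("weight" means importance, not
direction) and min-max scaled to [0, 1] per factor; the feature with the
maximum normalised weight per factor is that factor's *essential feature*
(ties break lexicographically, duplicates collapse). Identifiability
caveat: with only two indicators per factor the within-block loading
ordering is not identified (only the loading product is constrained), so
essential-feature recovery is only meaningful with three or more
indicators per factor.

For the clustering overview, per-layer factor scores are concatenated,
log10(OS + 1) is appended, columns are z-scored, and samples are clustered
by average-linkage on Euclidean distances.

## Classifiers and the diverse-subset split

Training and testing sets come from farthest-point ("Diverse Subset")
sampling run independently inside each class on the z-scored essential
profile: a seeded random first pick, then the farthest sample, then
repeatedly the sample with the largest mean distance to the selected set,
until ceil(2/3 × class size) samples are in training. The geometry matters:
the training set absorbs each class's extremes (including label-noise
outliers), leaving a testing set of class centres.

Six classifier families are wrapped behind one interface: L2-penalised
logistic regression (LR), RBF SVM with probability outputs, Gaussian naive
Bayes, a single-hidden-layer neural network (100 units, weight decay
1e-3), a 100-tree random forest, and ordinary least squares on the 0/1
label with scores clipped to [0, 1] (LiR). Features are z-scored with
training-set constants only; the constants travel with the model, so test
statistics can never leak into the transform. The LR penalty (1 on the
summed log-loss, intercept unpenalised — the sklearn `C = 1` convention)
is load-bearing: diverse-subset training sets are frequently linearly
separable, where the unpenalised logistic MLE diverges and produces
unstable rankings.

When omics combinations are compared, one split computed on the full
quadruple essential profile defines a single shared testing set and every
combination refits on its own feature subset. Per-combination splits would
evaluate each single-layer model on its own class centres, saturating the
continuous layers at AUC 1.0 and reducing the comparison to a coin flip
on mutation-layer noise.

AUC is the Mann–Whitney concordance probability (ties count one half),
computed from the threshold-sweep ROC.

## Target regulation simulation

For the quadruple-omics model, the *eligible* samples are the
confusion-matrix true negatives of the testing set: observed poor
prognosis and predicted poor prognosis. Each single essential feature and
each unordered pair (n + n(n−1)/2 specifications) is *down-regulated* in
every eligible sample to the minimum value of that feature over all
label-positive samples (train and test; the larger set stabilises minima).
For a mutation feature whose positives are all unmutated, the clamp is 0 —
regulation is mutation removal. The perturbed sample is re-standardised
with the model's stored constants and re-predicted; a re-prediction to
good prognosis is a *flip*. Pairs are evaluated even when both singles
already flip everyone (no pruning; fidelity is cheap at ~100 features).

The flip network has a node per feature with at least one flipping
specification (sized by the number of distinct patients affected), an edge
per flipping pair (weighted by flip count), and a per-feature
pair-participation count that ranks the TRS-essential biomarkers; the
default report takes the top of that ranking and the caller picks k.

## Risk scoring and survival analysis

The PRS is ordinary least squares of the 0/1 label on the biomarker
profile (linear regression is deliberate: scores are risk-like, not
probabilities). Features are standardised before fitting and the constants
stored, making coefficients comparable across biomarkers. The decision
threshold maximises Youden's J over midpoints of the sorted unique scores,
ties resolving to the lowest threshold. The package also ships
`published_prs()`, the 13-biomarker colon-cancer score with its printed
coefficients (intercept 0.325, threshold 0.254), evaluated directly on
supplied feature values.

Kaplan–Meier curves, the one-degree-of-freedom log-rank test and Cox
proportional-hazards screens are delegated to the `survival` package
(Efron tie handling for Cox; a sample censored exactly at an event time
remains in that risk set, the product-limit convention). Conventions:
no events at all gives log-rank statistic 0 and p = 1; median splits send
ties to the low group; Cox rows that fail to converge or separate
completely are flagged unestimable rather than crashing; stratified
biomarker screens skip strata below 4 samples with a warning. The default
age stratification cutoff is 65 years and is configurable.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of a multi-omics
tumour cohort with survival follow-up:

* a provisional poor-prognosis indicator is drawn per sample (fair coin);
* continuous layers are i.i.d. log-normal noise (`sdlog` 0.5, per-feature
  `meanlog` uniform on [0, 3]); planted features shift by
  `effect_size × sdlog` on the log scale in the provisional poor group;
* methylation is generated on the logit scale (sd 0.8, baselines uniform
  on [−2, 2]) and inverse-transformed, keeping beta values in [0, 1];
  planted probe baselines are drawn from the lowly methylated range
  [−2, −0.5] so that a d = 1.5 logit shift is visible as a beta-scale
  fold change (biologically: hypermethylation of lowly methylated probes);
* mutations are Bernoulli(0.05) background; planted mutation features are
  Bernoulli(`mutation_rate_negative`) in provisional-poor samples and 0
  elsewhere;
* the latent risk is the standardised sum of z-scored planted values; OS
  is exponential with hazard
  `baseline_hazard × exp(risk_coefficient × latent_risk)`, plus
  administrative censoring (uniform over follow-up) with probability
  `censor_rate`;
* the final prognosis label is recomputed from the drawn OS, so planted
  effects are attenuated realistically instead of separating the groups
  by construction; planted mutations are then zeroed in every final
  good-prognosis sample, making mutation exclusivity exact.

Defaults, chosen once as the package's study conditions: 200 samples,
300/300/300/150 features with 10/10/10/8 planted, effect size 1.5,
mutation rate 0.3, baseline hazard 5e-4 per day (median OS ≈ 1,386 days,
near the 1,825-day threshold), risk coefficient 2.5 per SD of latent risk,
censoring 20%. The risk coefficient is set high enough that the OS-derived
labels realise the planted between-group effect size — the generator's
contract — while the survival draw still injects label noise.

What the generator does **not** model: feature–feature covariance beyond
the shared group effect (no linkage or co-methylation structure), batch
effects, copy-number or proteomic layers, non-exponential baseline
hazards, informative censoring. Passing tests therefore demonstrate that
the pipeline recovers planted marginal group effects under realistic
attenuation and noise — not that it handles correlated noise, confounding
or batch structure in real cohorts.

## Verification strategy and problem sizes

Every core statistic is checked against an independent brute-force oracle:
Welch *t* against `stats::t.test`, the exact Wilcoxon *p* against full
rank-assignment enumeration, Kaplan–Meier against an explicit product over
risk sets, log-rank against manual risk-table arithmetic and a
label-permutation null, AUC against exhaustive pair counting, the greedy
diverse-subset rule against stepwise argmax enumeration, and TRS flip
decisions against from-scratch logistic score recomputation. Recovery
suites run at the scales the package treats as its study conditions:
screening power and ranking over 50 seeded cohorts (n = 200), type-I
calibration on 5,000 null features (binomial 99% bounds around 1%), EFA
loading recovery on 2-factor simulations (n = 500, tolerance 0.15),
dominant-driver TRS recovery over 25 seeds, Cox log-hazard recovery
(true log-HR 0.7, n = 300, 50 seeds, tolerance ±0.2), and the
multi-omics ordering over 20 seeded cohorts. These sizes keep the full
suite in the tens of seconds on a single CPU while leaving the assertions
statistically stable.

## Known limitations

* The screening FC gate is uninformative for binary mutation features
  (see above); a two-proportion test would be the natural refinement.
* Kaiser retention is sensitive to sampling noise near eigenvalue 1; the
  factor counts it yields are not comparable across cohorts of different
  sizes.
* TRS flips are classifier-relative: a flip certifies sensitivity of the
  fitted decision function, not a causal claim about the feature.
* The PRS is fit by OLS on a binary label; its scores are rankings, not
  calibrated probabilities.
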
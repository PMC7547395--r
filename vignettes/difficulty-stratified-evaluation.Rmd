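---
title: "Difficulty-stratified evaluation of clinical classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Difficulty-stratified evaluation of clinical classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdistrat)
```

## The problem

A single scalar metric — accuracy, AUC, F1 — summarizes a classifier over a
whole cohort and hides *which* cases it succeeds or fails on. In clinical
prediction this matters: a model that is excellent on obviously-sick and
obviously-well patients but no better than chance on ambiguous ones looks
respectable on average, yet the ambiguous patients are exactly where a
prediction would be most useful.

`cdistrat` makes case difficulty a first-class quantity. It scores every
case with a **classification difficulty index (CDI)** estimated from the
case's clinical features alone — the outcome label is never consulted — and
then reports classifier accuracy *within difficulty strata*, so two models
can be compared on easy and hard cases separately.

## The difficulty model

Each clinical feature is first dichotomized into a disease-promoting
indicator: a lab outside its normal range, age above 65 years, a
pre-existing condition present, and so on (see `feature_spec()`). The
resulting cases-by-items 0/1 matrix is modeled with a two-parameter
logistic (2PL) item response model: conditional on a latent
"unhealthiness" trait $\theta$, item $i$ is out of range with probability

$$P_i(\theta) = \frac{1}{1 + e^{-a_i(\theta - b_i)}},$$

where the slope $a_i$ (discrimination) measures how sharply the feature
separates cases along the trait and the location $b_i$ is the trait value
at which the feature is 50% likely to be deranged. The population is
anchored to $\theta \sim N(0,1)$, which identifies the scale: low $\theta$
is the healthy end, high $\theta$ the unhealthy end. Items with fitted
$|a_i| < 0.35$ are flagged as effectively non-discriminatory.

A case whose features are *mixed* — some deranged, some normal, in a
pattern that many items are ambivalent about — lands near $\theta = 0$ and
is hard to classify; a case far out in either tail is easy. The CDI is the
case's posterior mean of $\theta$ (expected a posteriori, EAP), with the
posterior SD as its per-case standard error.

### Estimation

`cdi_irt()` fits the model by marginal maximum likelihood with the
Bock–Aitkin EM algorithm. The latent trait is integrated on a fixed grid
of 61 equally spaced nodes on $[-6, 6]$ carrying renormalized
standard-normal weights; at desk scale this reproduces a 10,001-node
quadrature to well below $10^{-3}$ on EAP scores (the test suite checks
this directly). The E-step places each case's posterior mass on the grid;
the M-step refits each item's logistic curve to the expected node-level
counts by Newton iterations with step-halving. The marginal log-likelihood
is monotone non-decreasing across iterations, and convergence is declared
when no parameter moves by more than `tol` ($10^{-4}$ by default, at most
500 iterations; a non-converged fit is flagged on the object, not hidden).

Numerical guards: slopes are bounded at $|a| \le 10$ and locations at
$|b| \le 6$, which keeps quasi-Guttman items (nearly deterministic
response patterns) finite without affecting realistically noisy items —
published severity-feature slopes as steep as 5.6 sit comfortably inside
the bound. Starting values are $a = 1$ and a probit-approximation location
from each item's marginal proportion; constant item columns are rejected
with an error naming the item. No sign constraint is placed on slopes, so
reverse-indicating features are representable. Standard errors come from
the per-item observed information at the solution (delta method for $b$).

### Binning and collapsing

CDIs are grouped into half-open 0.5-wide strata centered on multiples of
0.5, the first bin centered at 0.0 (the hardest cases). The edge rule is
left-closed everywhere — a score of exactly $+0.25$ belongs to bin
$+0.5$, $-0.25$ to bin $0.0$ — which makes binning a single deterministic
formula, `width * floor(theta/width + 0.5)`. Extreme bins with fewer than
`min_count` cases (default 30) are merged inward until every remaining
extreme stratum is large enough; interior bins are never merged. The
default of 30 is the usual smallest group size at which a per-stratum
proportion is worth comparing; it is configurable.

## The classifier bench

`run_cv_bench()` evaluates six standard classifiers — logistic regression,
linear discriminant analysis, K-nearest neighbors, a decision tree,
Gaussian naive Bayes, and a single-hidden-layer neural network — under
stratified 10-fold cross-validation on the *original-valued* (imputed)
feature matrix. The essential discipline is per-case prediction tracking:
every case's probability comes from the one model that never saw it, and
stays linked to the case id so correctness can later be stratified by CDI
bin. Features are z-scored with training-fold statistics for the scale
sensitive learners (LR, LDA, KNN, NN); the tree and naive Bayes see raw
values. The decision threshold on the class-1 probability is 0.5.

The KNN predictor is a plain vote-share implementation supporting
Minkowski, Manhattan and Hamming distances, because no installed R
backend offers that metric family; `grid_search()` tunes K (1–40) and the
metric by cross-validated accuracy, with ties going to the smaller model.
The neural network is `nnet`: one hidden layer of logistic units trained
by BFGS with an L2 weight penalty, so its tunable axes are the hidden
size $\{1, 5, \ldots, 30\}$ and the decay $\{0.01, 0.1, 0.5, 1, 2\}$
rather than the activation-function and learning-rate axes a stochastic
gradient framework would expose. The default decay of 1 reflects the
regime these cohorts live in — a couple dozen noisy features, several of
them nearly pure noise — where an unregularized net reliably overfits its
training folds. Grid search is available in two modes: `"nested"` scores
configurations by inner 5-fold CVs run strictly inside each outer
training fold (no selection leakage into the outer folds), and
`"pooled"` scores them by a single k-fold pass over the full data, which
mirrors the common single-pass practice. Neither mode is asserted to be
the only defensible one; nested is the default.

## The stratified report and its tests

`stratified_accuracy()` is deliberately simple — mean correctness per
(bin, classifier) — and satisfies an exact consistency bridge: bin
accuracies weighted by bin counts rebuild each classifier's overall
accuracy to machine precision.

Significance testing uses a fixed-effects binomial logistic model of the
per-(case, classifier) correctness indicator,
`correct ~ bin * classifier`, fitted by iteratively reweighted least
squares (`glm`). A repeated-measure random-effects machinery is not
reimplemented here: with all effects fixed and a diagonal repeated-measure
covariance, the model is operationally a binomial GLM with working
independence, and that reduction is stated in the report header the
pipeline writes. Omnibus Wald chi-square tests (with equivalent F values)
use sum-to-zero contrasts, the Type-III convention of the mixed-model
packages this replaces; the difficulty-bin reference category is the 0.0
stratum. Estimated marginal means are averages of cell logits,
back-transformed to accuracies. All pairwise contrasts — bin margins,
classifier margins, and classifier pairs within each bin — are Wald z
tests reported at the conservative $\alpha = 0.001$, with no further
multiplicity correction beyond that threshold. Cells with 0% or 100%
correctness make sample logits infinite; they are flagged and the model is
refitted with a small ridge ($\lambda = 10^{-4}$) so every coefficient is
finite, with the flag propagated to the output.

The post-hoc inspector `hard_bin_feature_chisq()` crosses each feature's
in/out-of-range coding with correctness inside one chosen bin (Pearson
chi-square, df 1, no continuity correction), ordered by p with an optional
FDR column — a tool for asking *why* the hard cases elude a classifier.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces cohorts with exactly the structure the
method assumes: $\theta_j \sim N(0,1)$; binary indicators
$u_{ij} \sim \text{Bernoulli}(P_i(\theta_j))$; continuous raw values
emitted from truncated normals inside the feature's normal range when
$u_{ij} = 0$ and from a two-sided truncated mixture strictly outside it
when $u_{ij} = 1$, so that `dichotomize()` recovers the latent indicators
exactly; and mortality
$y_j \sim \text{Bernoulli}(\text{logit}^{-1}(c\,\theta_j + c_0))$.
The default item bank has 24 items mirroring a severity-score panel:
slopes spread log-normally around 1 plus one deliberately near-null item
(slope 0.15, the urine-output analogue), locations spanning the latent
range.

Two emission choices deserve explanation:

* **Asymmetric derangement.** Out-of-range values fall above the normal
  range 80% of the time (`low_mix_weight = 0.2`). Real severity labs
  derange predominantly in one direction in the critically ill, which is
  what gives raw values their monotone relation to unhealthiness; a
  50/50 emission would leave the binary indicators unchanged but strip
  the raw values of linear signal, producing cohorts on which linear
  classifiers cannot learn at all — unlike any real ICU data set.
* **Outcome-link calibration.** `calibrate_link_slope()` root-finds the
  slope $c$ so the expected point-biserial correlation between the CDI
  and the outcome matches a target (0.37 by default, a representative
  published value for a balanced ICU cohort). It uses common random
  numbers — one pool of traits, responses and EAP scores, with outcomes
  re-thresholded from a fixed uniform draw per candidate slope — so the
  correlation is smooth and monotone in $c$ and the root is sharp. At
  the default intercept of 0 mortality is ~50% (a balanced analysis
  set); set `link_intercept` negative to create a pool with minority
  mortality for the sampling designs (e.g. $-1$ gives roughly 27%).

The generator does *not* emulate: correlation between labs beyond what
the single latent trait induces (no local dependence), longitudinal
trajectories, informative missingness (only MCAR is provided), or
multi-site unit heterogeneity. Passing tests on these cohorts therefore
demonstrate the *machinery* — estimation, scoring, stratification,
testing — under the model's own assumptions; they do not certify
performance on real data, where local dependence and informative
missingness can bias both item parameters and CDIs.

## Sampling designs and imputation

`design_sample()` reproduces the two standard undersampling designs:
balanced keeps all $d$ deaths plus $d$ randomly drawn survivors
($2d$ total, 1:1) and imbalanced keeps $d$ deaths plus $2d$ survivors
($3d$ total, 1:2), both without replacement and deterministic given the
seed. Every death case appears exactly once in either design, so a
balanced/imbalanced pair drawn from one pool (`make_design_pair()`)
shares its death cases — the paired structure the comparison of designs
relies on.

Imputation is single-imputation chained equations: numeric columns are
initialized at observed means and re-imputed over `n_sweeps` passes by
stochastic linear regression on the other features (prediction plus a
residual draw, preserving spread). One completed data set is produced,
not several — the stratified analysis consumes a single analysis set, so
between-imputation variance is not propagated; this understates
imputation uncertainty and is a known limitation. Imputation runs once,
cohort-wide, before dichotomization, and both the binary matrix and the
classifier matrix see identical imputed values. Whether imputation should
instead run after design sampling is genuinely open; imputing first uses
all available information and keeps the design pair consistent.

## Numerical and design choices, collected

* Quadrature: 61 nodes on $[-6,6]$; EAP shrinkage keeps scores well
  inside (±2.5 for ~99% of cases when slopes are moderate).
* Range-endpoint convention: a value exactly at a normal-range endpoint
  is *in range* (coded 0); "outside the range" is read strictly.
* Bin edges: left-closed half-open intervals (see above); deterministic.
* EAP rather than a modal (MAP/ML) score: the posterior mean exists for
  every response pattern including all-0 and all-1, and its posterior SD
  is the natural per-case standard error.
* Decision threshold 0.5; classifiers failing on a fold are recorded as
  failures and the bench continues.
* Problem sizes used by the validation suite: parameter recovery at
  5,000 cases × 20 items; the end-to-end stratified run at 8,000 cases ×
  24 items with a 2-point NN grid; the null-calibration of the
  interaction test at 200 replicates of 2,000 cases × 6 classifiers.
  These sizes give stable Monte-Carlo margins for every property checked
  while keeping a full validation run in minutes on one core.

## Known limitations

* The 2PL is unidimensional; genuinely multidimensional unhealthiness
  (e.g. separate renal and respiratory axes) is projected onto one trait.
* Dichotomizing labs at range bounds discards severity information within
  the out-of-range region; a graded (polytomous) model would be the
  natural refinement.
* Single imputation, MCAR only (see above).
* The effect model treats repeated measures (six classifiers per case)
  with working independence; standard errors for classifier contrasts are
  approximate to the extent correctness is correlated across classifiers
  within case.
* IRT scale indeterminacy means CDIs are comparable within one fitted
  cohort, not across cohorts; each data set carries its own difficulty
  fingerprint.
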
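# cdistrat

Difficulty-stratified evaluation of clinical classifiers via item
response theory.

## What problem this solves

Scalar metrics (accuracy, AUC, F1) average a classifier's behavior over a
whole cohort, hiding that most of its errors concentrate on a particular
kind of case. `cdistrat` scores every case's **classification difficulty
index (CDI)** from its clinical features alone — the outcome is never
used — and then evaluates classifiers *within difficulty strata*, so you
can see whether a model that wins on average also wins on the ambiguous
cases where a prediction actually matters. It is aimed at researchers
benchmarking prediction models on tabular clinical cohorts (ICU mortality
being the motivating setting).

## The model

Features are dichotomized into disease-promoting indicators (lab outside
its normal range, age > 65, comorbidity present, ...). The cases × items
0/1 matrix is fitted with a two-parameter logistic (2PL) item response
model: given a latent "unhealthiness" trait θ ~ N(0, 1),

    P(u_i = 1 | θ) = 1 / (1 + exp(-a_i (θ - b_i)))

with discrimination `a_i` and location `b_i` per feature, estimated by
marginal maximum likelihood (Bock–Aitkin EM on a 61-node quadrature
grid). Each case's CDI is its expected-a-posteriori θ with a per-case
posterior-SD standard error. Cases near θ = 0 have ambiguous feature
patterns and are hard to classify; peripheral cases are easy. CDIs are
grouped into 0.5-wide bins centered at 0.0, sparse extreme bins collapse
inward, and six cross-validated classifiers (LR, LDA, KNN, decision
tree, naive Bayes, neural net) are compared per bin, with a
fixed-effects binomial logit model (`correct ~ bin * classifier`)
supplying Wald tests and α = 0.001 pairwise comparisons.

## Worked example

Everything below runs on a synthetic cohort with known ground truth
(2,000 cases × 24 ICU-style features; mortality linked to the latent
trait with point-biserial ≈ 0.37):

```r
library(cdistrat)

gen   <- generate_cohort(generator_config(n_cases = 2000, link_slope = 0.96), seed = 7)
coded <- code_cohort(gen$cohort, gen$specs, seed = 8)

fit <- cdi_irt(coded$binary_matrix)
fit
#> Two-parameter logistic difficulty model (marginal ML)
#>   2000 cases x 24 items; log-likelihood -27839.48 (19 EM iterations)
#>   1 item(s) flagged non-discriminatory (|a| < 0.35)

sc <- cdi_scores(fit)              # CDI, SE, difficulty bin per case
cdi_descriptives(sc$cdi, coded$outcome)
#> CDI descriptives (n = 2000)
#>   range -2.55 to +2.33; mean 0.00 (SD 0.92)
#>   no death -0.35 (SD 0.85); death 0.36 (SD 0.83)
#>   point-biserial r = 0.387 (p = 1.26e-72); t(1998) = 18.78 (p = 1.26e-72)

rec <- run_cv_bench(coded, k_folds = 10, seed = 9)
stratified_accuracy(rec, sc)
#> Mortality-prediction accuracy stratified by difficulty bin (%)
#>  n_cases cdi_bin   LR  LDA  KNN   DT   NB   NN
#>       39     2.0 79.5 79.5 84.6 82.1 82.1 71.8
#>      144     1.5 72.9 72.9 77.8 79.9 80.6 66.7
#>      266     1.0 63.5 63.2 61.3 70.3 72.2 60.9
#>      367     0.5 57.2 56.7 50.4 53.1 57.5 54.8
#>      388     0.0 55.7 55.7 59.5 48.5 57.0 54.1
#>      365    -0.5 58.6 58.9 61.9 57.5 60.0 56.7
#>      257    -1.0 71.2 71.2 72.0 69.6 72.0 65.0
#>      117    -1.5 77.8 77.8 77.8 76.9 77.8 73.5
#>       57    -2.0 91.2 91.2 91.2 91.2 91.2 89.5

fit_effect_model(rec, sc)
#> Fixed-effects binomial logit model: correct ~ bin * classifier
#>          effect wald_chisq df f_value   df2        p
#>             bin     400.47  8   50.06 11946 1.48e-81
#>      classifier      10.12  5    2.02 11946 7.20e-02
#>  bin:classifier      36.04 40    0.90 11946 6.49e-01
```

Reading the table: accuracy is parabolic in the CDI bin — every
classifier is weakest in the central (hardest) strata, around 48–60%,
and climbs toward 80–91% in the peripheral bins, and the bin main effect
dominates the omnibus tests. Classifiers that tie on overall accuracy
can differ visibly inside specific strata, which is the comparison this
package exists to expose. `hard_bin_feature_chisq()` then asks, feature
by feature, what distinguishes the correctly from the incorrectly
classified cases inside a chosen bin.

A full run (simulate/load → code → fit → score → bench → evaluate,
with CSV/JSON/plot artifacts and a manifest) is one call:

```r
run_pipeline(list(
  generator = list(n_cases = 4000, link_slope = 1, link_intercept = -1),
  design = "both", seed = 1, outdir = "out"
))
```

or from a shell via the thin wrapper `inst/cli/cdistrat.R` with a YAML
config.

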
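# ibpcog

Latent neurocognitive features via the Indian Buffet Process, with
dependent-correlation comparisons against risky/impulsive-behavior outcomes.

## The problem

Neurocognitive batteries measure many overlapping subfunctions (attention,
working memory, inhibition, episodic memory, ...) across instruments.
Analyzing each score separately ignores that subfunctions co-occur within
people, and fixed-dimension methods (factor analysis, latent profile
analysis) require choosing the number of components in advance. `ibpcog`
models a standardized battery `X` (N participants × D measures, z-scored,
with missing cells) with a **linear-Gaussian Indian Buffet Process (IBP)**:

    X = Z A + E,   E[i, d] ~ N(0, σ_X²)
    Z ~ IBP(α)     (N × K binary; K is inferred, not fixed)
    A[k, d] ~ N(0, σ_A²)

Rows of `Z` say which latent features each person samples; rows of `A` say
how each feature expresses across the D measures. The IBP prior lets the
number of features K grow or shrink with the data: the expected feature
count is `α·H_N` (H_N the N-th harmonic number). Inference is by Gibbs
sampling with the weights integrated out of the row updates ("accelerated"
sampling), which handles per-cell missingness exactly because the collapsed
marginal factorizes over measures. `α` has a conjugate Gamma update; the
noise scales have conjugate inverse-gamma updates (a log-scale Metropolis
variant is available). Per-person **continuous feature values** in [0, 1] —
the full-conditional probability of sampling each retained feature — are the
unit of analysis downstream.

Downstream, features sampled by at least 5% of participants are retained
(`floor(0.05 × 673) = 33` people in a 673-person sample), profiled as
per-measure mean z-scores, checked for demographic balance (ANOVA for age,
chi-square for sex and race/ethnicity), and correlated with behavioral
outcomes. Whether one feature correlates more strongly than another with
the same outcome is tested with **overlapping dependent-correlation tests**
(Steiger/Dunn–Clark z by default; Williams' t and Zou's confidence interval
as alternatives), Bonferroni-corrected by outcome family (2
impulsive-behavior measures, 4 substance-use measures).

A synthetic-data module generates batteries, outcomes and demographics from
a planted model with known ground truth, so every stage — including
parameter recovery of `Z`, `A`, `σ_X` — is testable without restricted data.

## Worked example

Simulate a 400-person battery from a planted 5-feature model with two
outcomes (one impulsive-behavior, one substance-use), then run the full
pipeline — preprocess, sample, filter, profile, correlate:

```r
library(ibpcog)

cfg <- synthetic_config(
  n_participants = 400, planted_k = 5, membership_probs = 0.2,
  noise_sd = 0.5, missing_rate = 0.05,
  outcome_specs = list(
    list(name = "negative_urgency", family = "impulsive_behavior",
         rho = c(0.25, 0, 0, 0, 0)),
    list(name = "cannabis_use", family = "substance_use",
         rho = c(0, 0.2, 0, 0, 0))),
  seed = 20)

result <- run_pipeline(synthetic = cfg, sweeps = 50, seed = 11)
print(result)
#> <pipeline_result> N = 400, D = 27: final K = 14, 7 feature(s) retained (threshold 20)
#> <comparison_table> 14 correlation(s), 42 pairwise comparison(s) [steiger],
#>   9 significant after Bonferroni
```

The sampler's final state and trace:

```r
print(result$fit)
#> <ibp_fit> 50 sweeps (seed 11001): K = 14, alpha = 2.45, sigma_x = 0.85, sigma_a = 0.46
```

Fourteen features exist at the final iteration, but most are sampled by a
handful of people; seven pass the 5% filter (threshold 20 of 400). On the
z-scored battery the noise scale settles near 0.85 and the weight scale near
0.46 — most variance is idiosyncratic, features carry structured residual
patterns.

Feature–outcome correlations (one planted feature was given population
correlation 0.25 with `negative_urgency`; its sample estimate is 0.26):

```r
head(result$comparison$correlations[, c("outcome", "feature_id", "r", "p_adjusted")], 5)
#>            outcome feature_id       r p_adjusted
#> 1 negative_urgency  feature_1  0.0389    8.8e-01
#> 2 negative_urgency  feature_2  0.2639    1.7e-07
#> 3 negative_urgency  feature_3  0.0071    1.0e+00
#> 4 negative_urgency  feature_4 -0.0254    1.0e+00
#> 5 negative_urgency  feature_5  0.0279    1.0e+00
```

Which features correlate *differently* with the outcome (dependent
overlapping correlations, Bonferroni-adjusted within family):

```r
subset(result$comparison$comparisons, significant_adjusted,
       select = c(outcome, feature_j, feature_k, statistic, p_adjusted))
#>           outcome feature_j feature_k statistic p_adjusted
#>  negative_urgency feature_1 feature_2     -3.31   1.84e-03
#>  negative_urgency feature_2 feature_3      3.65   5.15e-04
#>  negative_urgency feature_2 feature_4      4.10   8.37e-05
#>  ...
```

`feature_2` (the planted urgency-linked feature) beats every other retained
feature on `negative_urgency`; the signs follow `r_jy - r_ky`.

Recovery against the planted truth on the model scale:

```r
ds  <- generate_dataset(synthetic_config(n_participants = 300,
                                         raw_shift = FALSE, seed = 1))
fit <- run_ibp(ds$battery, sweeps = 50, seed = 101)
recovery_report(ds, fit)
#> <recovery_report> modal K = 6, retained K = 5 (planted 5)
#>   sigma_x: 0.504 vs planted 0.500 (rel. error 0.8%)
#>   matched AUCs: 1.000, 1.000, 0.999, 0.999, 0.952
```

All five planted features are recovered above the count filter (plus one
low-count transient feature — expected IBP behavior, and the reason the
filter exists); memberships are near-perfectly ranked by the continuous
feature values, and the noise SD is recovered within 1%.

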
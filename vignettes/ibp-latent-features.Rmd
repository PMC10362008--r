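---
title: "Latent feature analysis of neurocognitive batteries: model, sampler, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent feature analysis of neurocognitive batteries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibpcog)
```

## The model

`ibpcog` fits a linear-Gaussian latent feature model to a standardized
neurocognitive battery. Let `X` be the N × D matrix of z-scored measures
(with an explicit missingness mask), `Z` an N × K binary matrix of feature
memberships and `A` a K × D matrix of feature-to-measure weights:

$$X = Z A + E, \qquad E_{id} \sim N(0, \sigma_X^2), \qquad
  A_{kd} \sim N(0, \sigma_A^2).$$

`Z` carries an Indian Buffet Process prior with concentration `alpha`. In
the buffet construction, customer 1 samples `Poisson(alpha)` dishes and
customer *i* samples existing dish *k* with probability `m_k / i` and
`Poisson(alpha / i)` new dishes; the expected total feature count is
`alpha * H_N`. The prior makes K data-driven rather than pre-specified,
which is the point: a battery of 27 measures spanning attention, working
memory, inhibition, episodic memory, social cognition and processing speed
does not come with a known number of co-occurrence patterns.

Two conventions deserve note. First, the noise parameters are **standard
deviations** throughout (`sigma_x`, `sigma_a`), the usual scale
parameterization of the linear-Gaussian IBP; reported magnitudes like 0.9
and 0.4 for a z-scored battery read naturally on this scale. Second, the
mask is explicit: masked cells carry no information anywhere in the
likelihood, never a sentinel value.

## Preprocessing

The bundled schema describes the 27-score battery: twelve D-KEFS scores,
the three ANT time-based efficiency scores (the only reverse-scored
measures: lower times are better), eight Penn CNB efficiency scores, Digit
Span forwards/backwards, and RAVLT delayed recall. The pipeline applies, in
order:

1. **Direction conventions** — reverse-scored columns are negated so higher
   always means better. Negation is an involution, so the operation is
   self-inverse.
2. **Finger-tapping plausibility filter** — tapping sum scores below 10 or
   above 151 are replaced as missing (boundary values retained); such
   values indicate recording faults, not performance.
3. **Column z-scoring** — each measure is centered and scaled by the mean
   and sample SD (denominator n − 1) of its *unmasked* cells.

The order is a design choice: filtering precedes standardization so
implausible values cannot contaminate the column statistics. The z-scoring
denominator (n − 1 rather than n) is likewise a choice; at the sample sizes
involved the difference is negligible, but it is recorded and tested.

## The Gibbs sampler

Inference is by Gibbs sampling over `(Z, A, alpha, sigma_x, sigma_a)`.

**Row updates (default: `method = "accelerated"`).** Memberships are
updated row by row with the weights integrated out. For feature *k* with
popularity `m` excluding row *i*,

$$P(z_{ik} = 1 \mid \text{rest}) =
  \frac{(m/N)\,L_1}{(m/N)\,L_1 + (1 - m/N)\,L_0},$$

where `L_1`, `L_0` are marginal likelihoods of row *i*'s unmasked cells
under the weight posterior computed from all *other* rows. With missing
data this collapsed marginal factorizes over measures — each measure's
weight column has a Gaussian posterior built from exactly the rows observed
in that measure — so per-cell missingness is handled without imputation.
Features sampled only by the current row ("singletons") are removed and
their count redrawn as one blocked move from a truncated
`Poisson(alpha / N)` times the marginal likelihood with the new weights
integrated against their prior; the truncation cap (`k_cap`, default 4 per
row, plus an optional global `max_k`) bounds per-row work. The blocked
removal-plus-redraw is atomic: no other update intervenes between them,
which is required for the kernel to leave the posterior invariant.

An **explicit-weights variant** (`method = "explicit"`) conditions each
flip on the current draw of `A`. Both methods target the same posterior and
both are validated against exhaustive enumeration on small instances (see
below). In practice the collapsed updates mix dramatically better: at
realistic sizes the explicit-A chain can spend very long stretches in
"fragmented" states in which a true feature is covered by one main column
plus small satellite columns whose weights were just fit to their few
members — each single flip is locally unfavorable even though the whole
configuration has far lower posterior mass. Integrating the weights removes
the self-reinforcement and is the reason accelerated sampling is the
default.

**Weights.** `A` is redrawn once per sweep from its Gaussian full
conditional, measure by measure, using for measure *d* only rows unmasked
in *d*; a fully masked measure falls back to the prior. Masking a cell is
algebraically identical to deleting its likelihood term — a property the
test suite checks to numerical precision on random instances.

**Concentration.** `alpha` has a conjugate update:
`Gamma(shape + K, rate + H_N)` with a `Gamma(1, 1)` prior by default;
`alpha` is initialized at 5, which matters only for the first sweeps.

**Noise scales.** Given `(Z, A)`, both `sigma_x^2` and `sigma_a^2` are
conditionally conjugate under Jeffreys priors (flat on the log scale), and
the sweep uses exact inverse-gamma draws by default
(`scale_update = "conjugate"`). A one-step log-scale random-walk Metropolis
update (`resample_noise_scales`, proposal SD 0.1) is retained as an option;
it is correct but adapts slowly — roughly fifteen sweeps to travel from a
unit initialization to a posterior scale of 0.5 — which matters when the
fit budget is a few dozen sweeps.

**Initialization.** The chain starts from zero features by default
(`init = "empty"`; `init = "prior"` gives an overdispersed start from an
IBP draw). When the caller does not supply hyperparameters, `sigma_x` is
initialized at the overall SD of the observed cells — exactly 1 for a
z-scored battery, so the standard configuration is unchanged. This
empirical start matters at other scales: a `sigma_x` start far above the
data scale makes every new-feature proposal unattractive (the chain stalls
at K = 0 and the conjugate `alpha` update then collapses `alpha`), while a
start far below freezes early, arbitrary membership choices in place. The
marginal data SD starts the noise estimate where the no-feature model puts
it and lets it anneal downward as features are discovered.

**Trace and convergence.** The trace records, per sweep, K, `alpha`,
`sigma_x`, `sigma_a` and the joint log density; its first record is the
initial state (iteration 0), so the `alpha = 5` initialization is visible.
Convergence is reported, never enforced, as the length of the terminal
window over which K and `alpha` (rounded to 0.1) are constant. Feature
identity is not meaningful across runs (label switching); cross-run
comparisons go through cosine-similarity matching of weight vectors.

## Continuous feature values

For each person and retained feature the package reports the
full-conditional inclusion probability at the final iteration — a value in
[0, 1] expressing the extent to which the person samples the feature, the
probability reading of "continuous feature values". A fully masked row
reduces exactly to the prior `m / N`. An alternative reading — averaging
binary membership over a terminal window of sweeps — is available via
`run_ibp(value_window = ...)`, with feature identity tracked by stable
column ids within the window. Binary final-iteration memberships, not
thresholded probabilities, define the **sampling counts** used by the
filter.

## Feature filtering, profiles, demographics, stability

Features sampled by fewer than 5% of participants are dropped:
`inclusion_threshold(n, 0.05) = floor(0.05 n)`, e.g. 33 people at
n = 673. The floor convention is forced by that worked value. Retained
features are profiled as per-measure mean z-scores with standard errors
over members' unmasked cells. Demographic balance uses a one-way ANOVA for
age and chi-square tests of independence (no continuity correction) for sex
and race/ethnicity, comparing members against non-members per feature —
the member/non-member design is a recorded choice, as the grouping design
could also be read as comparing across features. Split-half stability
refits the model on seeded random halves and matches retained features
across halves by maximizing total cosine similarity under a one-to-one
assignment (exact by permutation enumeration up to eight features per side,
greedy beyond).

## Dependent correlations

Each retained feature's continuous values are correlated with each outcome
(Pearson, pairwise-complete, p from the t transform). Comparing two
features' correlations with the *same* outcome is a dependent,
overlapping-correlations problem: the estimates share `y` and the features
are themselves correlated (`r_jk`). The default statistic is the
Steiger/Dunn–Clark z on Fisher-transformed correlations with the covariance
term evaluated at the average of the two correlations — a widely
recommended choice for overlapping comparisons; Williams' t (df = n − 3)
and Zou's confidence interval are selectable. Which specific statistic the
original analyses printed is not recoverable from their description, so the
default is recorded as this package's choice. Each comparison is computed
on the subsample jointly observed on both features and the outcome, so the
correlation triple is internally consistent (and is validated as a positive
semidefinite 3 × 3 matrix). Bonferroni correction multiplies p by the
outcome-family size — 2 for impulsive-behavior measures, 4 for
substance-use measures — and caps at 1; no correction across feature pairs
is applied, since the analysis being reproduced describes none. For the
interval method, family correction widens the interval to level
`1 − alpha / m` instead.

## The synthetic generator

The generator plants a known model and emulates the study's data shape:
default 673 participants × 27 measures, 5 planted features (the number of
retained, interpretable features), independent Bernoulli memberships
(default probability 0.2, giving feature counts comfortably above the 5%
filter), block weights in which each feature loads on a disjoint set of
measures (`weight_scale = 1`), Gaussian noise (`noise_sd = 0.5`),
missing-completely-at-random cells (5%), outcomes linear in the planted
membership indicators with solvable target correlations (feasible when the
squared targets sum below 1), and demographics drawn independently of the
features with ages uniform on 18–55 and composition matching the study
sample (64% female; 67/21/6/6% race/ethnicity). Memberships use
independent Bernoulli draws rather than the IBP prior deliberately, so
popularity — and hence filter behavior — is controllable; the IBP prior
simulator is tested separately against its closed-form moments.

What the generator does *not* emulate: instrument-specific skew, floors and
ceilings; not-at-random missingness; correlated feature memberships.
Passing recovery tests therefore demonstrates correctness of the machinery
under the model's own assumptions, not robustness to real-instrument
pathologies.

Batteries are emitted on an instrument-like raw scale by default (per-column
shift and scale, with the finger-tapping column given a realistic 10–151
range) so the preprocessing stage is exercised end-to-end. **Parameter
recovery, however, is assessed on the model's natural scale**
(`raw_shift = FALSE`, no z-rescaling): z-scoring divides each column's
planted noise SD by a column-specific factor, after which no single
`sigma_x` is comparable to the planted value. This is a deliberate design
split — the pipeline is validated on raw-shifted data, the estimator on
model-scale data.

## What the oracles establish

The test suite validates the sampler against independent oracles rather
than against itself:

- the **collapsed marginal likelihood** against a closed-form bivariate
  normal density and against brute-force Monte-Carlo integration over the
  weights;
- the **stationary distribution** of both row-update methods against
  exhaustive enumeration of all binary matrices (IBP prior × collapsed
  marginal) on small complete-data instances, within total-variation 0.05;
- **prior moments** against `alpha * H_N` and Poisson(alpha) closed forms;
- **weight conditionals** against hand-computed conjugate updates and the
  masked-equals-deleted identity;
- the **dependent-correlation test** against an independently coded
  implementation of the published formula and against its simulated null
  distribution;
- **recovery** against planted ground truth at N = 300, D = 27, K = 5
  (50 sweeps, ten seeded runs): membership AUC, `sigma_x` error, and
  feature counts.

One recovery subtlety is worth stating plainly because it mirrors the
applied behavior of this model class: with hyperparameters resampled, the
posterior over the *raw* feature count K sits 1–3 above the planted K —
low-count transient features ride along with the real ones (the adapted
weight scale makes small features cheap). The same phenomenon appears in
applied IBP fits, where K stabilizes well above the number of features that
survive the 5% filter and several features are sampled by one or two
individuals. Accordingly, the *retained* feature count recovers the planted
K, while raw modal K typically lands one or two above it; the acceptance
suite asserts both, and the raw-K assertion documents this gap rather than
hiding it.

## Numerical choices and degenerate inputs

- Flip probabilities are computed via log-likelihood differences and the
  stable form `1 / (1 + ((N−m)/m) e^{−Δ})`; overflow in `e^{−Δ}` degrades
  gracefully to probability 0.
- Zero-variance or under-observed (< 2 cells) columns are hard errors at
  z-scoring, naming the measure.
- Correlations require ≥ 3 jointly observed pairs; comparisons require
  n ≥ 4 and strictly interior correlations; identical feature-value vectors
  short-circuit to statistic 0, p 1.
- An outcome with no observed values is excluded with a warning, never an
  error.
- A measure with no unmasked rows draws its weight column from the prior.
- Empty feature columns are pruned at the end of every sweep; the trace K
  always equals the retained column count.
- Matching uses exact assignment up to 8 features per side (enumeration of
  one-to-one maps), greedy beyond; similarities of zero-norm vectors are
  treated as 0.

## Problem sizes used by the test and acceptance runs

The suite runs at desk scale by choice: enumeration oracles on N ≤ 4, D ≤ 2
instances with 12,000–50,000 sweeps; recovery at N = 300, D = 27, K = 5
with 50 sweeps over ten seeds; calibration of the dependent test with 5,000
null replicates at n = 200; the planted end-to-end contrast with 200
replicates at n = 600. The full-size configuration (N = 673, D = 27) is the
generator default and runs in a few tens of seconds per fit.

## Known limitations

- The sampler is single-chain; multiple-chain diagnostics beyond the trace
  are out of scope.
- Continuous feature values condition on the final-iteration weights; they
  inherit that iteration's label identities and Monte-Carlo noise. The
  window-average option trades sharpness for stability.
- The dependent-correlation statistic choice (Steiger default) is this
  package's decision; printed p-values from analyses using a different
  overlapping-correlations statistic will differ in the third decimal.
- Raw K from an IBP fit is not an interpretable feature count; use the
  filtered count (see above).
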
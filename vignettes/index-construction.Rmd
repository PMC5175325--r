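---
title: "Constructing pharmaceutical-regulation indices with a Bayesian probit IRT model"
author: "pharmRegIRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing pharmaceutical-regulation indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

National pharmaceutical-regulation quality is a latent trait: it cannot be
observed directly, only through binary indicators such as "an MRA exists" or
"GMP requirements are published by the government". pharmRegIRT builds three
indices from such indicators — state regulatory infrastructure (14 items),
monitoring of the private market (26 items) and public quality control (18
items) — with a one-factor item response model, so that the data, not the
analyst, decide how much each indicator contributes to the index.

## Model and assumptions

For country $i = 1,\dots,N$ and item $j = 1,\dots,J$, a latent continuous
response underlies each observed binary response:

$$x^*_{ij} = \lambda_j \phi_i - \alpha_j + e_{ij}, \qquad
  e_{ij} \sim \mathrm{N}(0,1), \qquad
  x_{ij} = \mathbf{1}\{x^*_{ij} > 0\},$$

a probit two-parameter IRT model (equivalently a one-factor analysis model
for binary indicators, with the cut point fixed at zero because every item
is dichotomous). $\phi_i$ is the country's index score, $\lambda_j$ the
item's discrimination (factor loading) and $\alpha_j$ its difficulty
(intercept). The model assumes:

* one dominant latent dimension per index (items were grouped by design so
  that each set measures a single aspect of regulation);
* conditional independence of items given $\phi_i$;
* missing responses ignorable given the model (they are excluded from the
  likelihood, a missing-at-random treatment).

### Identification

The likelihood is invariant under the reflection
$(\Lambda, \phi) \to (-\Lambda, -\phi)$ and under rescaling of $\phi$. Scale
is fixed by the standard-normal prior on $\phi_i$; reflection is resolved by
constraining a single **anchor item's** discrimination to be positive. We
deliberately do not force all loadings positive: weakly related items can
legitimately have posterior discrimination mass on both sides of zero, and
the index tables are expected to expose such items rather than hide them.
The default anchors are the items with the strongest expected relationship
to each index (published GMP requirements; legal control of medicine
promotion; prequalification of products and suppliers); any item can be
chosen via `ModelConfig(anchorItem = )`. Flipping every response of a data
set approximately negates the difficulty and score estimates while leaving
discriminations in place, confirming the constraint resolves sign
invariance only (this is a test in the suite).

## Gibbs sampler

All full conditionals are conjugate after data augmentation:

1. **Augmentation** (`augmentLatent`): given current parameters, each
   observed $x^*_{ij}$ is drawn from $\mathrm{N}(\lambda_j\phi_i-\alpha_j, 1)$
   truncated to $(0,\infty)$ if $x_{ij}=1$ and $(-\infty,0]$ if $x_{ij}=0$.
2. **Scores** (`conditionalPhi`): $\phi_i \mid \cdot \sim \mathrm{N}(m_i, v_i)$
   with $v_i = (1 + \sum_{j \in \mathrm{obs}(i)} \lambda_j^2)^{-1}$ and
   $m_i = v_i \sum_{j \in \mathrm{obs}(i)} \lambda_j (x^*_{ij} + \alpha_j)$.
3. **Items** (`conditionalItem`): $(\lambda_j, \alpha_j)$ is a Bayesian
   linear regression of $x^*_{\cdot j}$ on $(\phi_i, -1)$ with independent
   normal priors; the exact bivariate-normal posterior is drawn, and for the
   anchor item $\lambda$ is drawn from its marginal truncated to
   $(0,\infty)$ followed by the exact conditional for $\alpha$.

Missing entries simply drop out of every sum, which is mathematically
equivalent to integrating them out under this model and avoids imputation
noise.

### Priors and chain defaults

Priors are independent $\mathrm{N}(0, 2^2)$ on every $\lambda_j$ and
$\alpha_j$: proper and weakly informative, comfortably bracketing the
magnitudes that arise for regulation surveys (discriminations up to about 4,
difficulties within about $\pm 3$). Default chain settings are 120,000
sweeps with 20,000 burn-in thinned by 10 — conservative settings for a
final analysis. All examples and tests use much shorter chains (typically
500 burn-in + 3,000 sweeps at $N = 78$), which this sampler's fast mixing
at survey scale makes adequate; `chainDiagnostics()` (Geweke z and
effective sample size via coda) is computed on every pipeline run so chain
adequacy is checked rather than assumed.

### Numerical choices

* Truncated normals are drawn by inverse-CDF; the uniform is clamped to
  $[10^{-16}, 1-10^{-16}]$ so that a linear predictor far from the cut
  point ($|\eta| \gtrsim 8$) yields a finite draw instead of an infinity.
* Initialization: $\alpha_j = -\Phi^{-1}(\bar x_j)$ from item prevalences
  (clamped to [0.02, 0.98]), $\lambda_j = 1$, $\phi$ standardized row means.
* Posterior SDs use the population (divide-by-$n$) convention.
* Quantiles (credible intervals, corner thresholds) use R's default
  continuous type-7 definition.
* Exact ties in rank probabilities count as "not greater"; they occur only
  with degenerate draws.
* Determinism: a run consumes a fixed number of random variates per sweep
  given the missingness pattern, so a seed fully reproduces a fit;
  `runPipeline()` derives all stage seeds from one master seed.

## The synthetic generator

The WHO survey responses underlying the published indices are not
redistributable, so the generator (`simulateResponses`,
`paperlikeScenario`) emulates them from the measurement model itself with
known ground truth: $N = 78$ countries, the exact item sets of the three
indices, discriminations uniform on $[0.2, 2.2]$ and difficulties uniform
on $[-1, 1.5]$ (ranges bracketing the posterior means published for all
three indices), standard-normal latent scores, and 5% missingness
completely at random.

What it does *not* emulate: informative nonresponse (the real survey's
missingness mechanism is unknown), correlation between a country's scores
across the three indices (each scenario draws fresh scores; the shared
latent-trait construction used in the acceptance script covers the
correlated case explicitly), and any clustering of items beyond the single
factor. Passing recovery and calibration tests on these data therefore
demonstrates the correctness of the estimation machinery under the model's
own assumptions — not that the model is right for the real survey.

## From draws to published quantities

* `summarizePosterior()` reproduces the index-table layout: items ordered
  by posterior mean discrimination, with items whose discrimination has a
  significant share of posterior mass below zero flagged and placed last.
  "Significant share" is not a published number; the default threshold is
  $P(\lambda_j < 0) \ge 0.10$, configurable and recorded in the summary
  object.
* `rankPairProbability()` and `extremeProbability()` are computed on joint
  draws, preserving the positive posterior correlation between country
  scores; marginal intervals overstate the uncertainty of comparisons.
  `extremeProbability()` takes an optional sub-universe so a country can be
  compared within any chosen group.
* `compareIndices()` reports the squared Pearson correlation of
  posterior-mean scores between two indices and a **corner-occupancy**
  count: the number of countries below the x-index's lower quartile and
  above the y-index's upper quartile. The published diagnostic is a visual
  "empty triangle"; a quantile rectangle is the testable, monotone-invariant
  operationalization, and the thresholds used are reported in the output.
  Country exclusions are always user-supplied and recorded, never automatic.
* Point scores are posterior means throughout; a draws-based posterior for
  cross-index R² is out of scope.

## The inspection-regularity composite

The private-market index contains one derived item built from
years-between-inspections for three market segments (manufacturers, retail
distributors, pharmacies/dispensing points). Two codings are modeled:
*regular* — all three segments inspected at least every three years, or any
segment inspected at least yearly; *annual* — all three segments inspected
at least yearly. The published material documents the first rule explicitly
and pairs it with an "annual inspections" model variant without printing
that variant's rule; the all-segments-within-a-year coding used here is the
natural strictly-harder counterpart (and the test suite verifies it is
pointwise no easier than the regular coding). Missing inspection data for
any segment makes the composite missing — inspections are never fabricated.
Sub-items carrying an "S" suffix are ordinary items; continuous survey
quantities other than the inspection frequencies are excluded from the
indices by design.

## Problem sizes in the test suite

Unit and acceptance tests run at the scales the science requires while
staying desk-sized: conditional-moment checks at $4\times10^4$ Monte-Carlo
draws; quadrature comparisons at 50,000 Gibbs draws per response pattern;
recovery at $N = 1000$ (RMSE) and $N = 78$ (correlation, three seeds);
interval calibration pooled over 200 simulated surveys with reduced chains
(300 burn-in + 1,000 sweeps); end-to-end determinism on a 30-country run.
These are the package's reference settings for reproducing its own checks.

## Known limitations

* The indices are *de jure*: they measure whether policies and institutions
  exist on paper, not how well they are enforced.
* Single-factor structure is assumed, not tested; multi-factor models and
  ordinal items are out of scope.
* With $J = 14$–26 binary items and $N = 78$, posterior uncertainty in
  $\phi$ is substantial; ranking statements should always be made through
  the rank-probability functions rather than point scores.
* Agreement with the published index values cannot be verified directly
  because the underlying survey responses are not available; all
  quantitative guarantees are therefore stated against synthetic data with
  known truth.
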
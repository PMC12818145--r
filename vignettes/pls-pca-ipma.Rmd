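---
title: "Composite path modeling with principal-component weights and IPMA"
author: "plsipa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite path modeling with principal-component weights and IPMA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsipa)
```

## The model

`plsipa` estimates a composite-based structural equation model. A small set
of latent constructs is connected by a *recursive* (acyclic) system of
directed paths,

$$\eta = B\,\eta + \Gamma\,\xi + \zeta,$$

where $\xi$ collects the exogenous latents (no incoming path), $\eta$ the
endogenous ones, $B$ and $\Gamma$ hold the structural coefficients and
$\zeta$ the equation disturbances. Each latent is measured reflectively by
a block of observed indicators, $x_i = \lambda_i L + \varepsilon_i$ with
$\mathrm{var}(\varepsilon_i) = 1 - \lambda_i^2$ on standardized scales.
Latent roles are derived from the adjacency rather than declared, so a
model specification cannot contradict itself; formative blocks are accepted
in the specification but only reflective evaluation statistics are
computed (a warning is emitted), because AVE and composite reliability are
defined only for reflective measurement. Single-indicator blocks are
treated as reflective with loading 1 — reflective and formative coincide
for them.

## One-shot principal-component weighting

A latent score is a weighted sum of its standardized indicators,
$t = Xw$. Classic composite estimators obtain $w$ from an iterative
inner/outer approximation loop run to a convergence threshold (typically
$10^{-5}$). The scheme implemented here is deliberately *one-shot*: $w$ is
the dominant eigenvector of the block covariance matrix,
$X^\top X w = \lambda w$, i.e. the first principal component, which
maximizes the variance extracted from the block. That vector is declared
the final weight vector; no iteration follows. The iterative loop and its
threshold are therefore documented here for contrast but intentionally not
implemented, and the path/centroid/factor inner-weighting schemes are out
of scope.

Numerical choices:

* **Eigen-extraction.** Blocks are small (rarely more than ten
  indicators), so a full symmetric eigendecomposition of the explicit
  block covariance matrix is used — no truncated or sequential
  (NIPALS-style) solver, since only the first component is ever needed.
* **Sign orientation.** Eigenvectors are sign-ambiguous. The component of
  largest absolute value is made positive (first such component on ties,
  with a relative $10^{-8}$ tolerance so that different numerical routes
  to the same direction orient identically). The rule is deterministic and
  dataset-independent; comparisons with other software may still differ by
  a global sign per latent.
* **Normalization.** The eigenvector is rescaled so the sum of absolute
  components is one. The raw score $Xw$ then does not have unit variance,
  so scores are re-standardized (sample variance, $n-1$ denominator)
  before loadings and regressions — loadings and path coefficients are
  thus standardized quantities. The abs-sum-one weights are retained for
  the importance–performance stage.
* **Degenerate inputs.** Zero-variance columns, rank-zero blocks,
  zero-variance scores and collinear parent sets are rejected with typed
  errors rather than silently perturbed; missing values are rejected
  (complete cases required — imputation is out of scope).

Outer loadings are indicator–score correlations; the structural
coefficients are per-equation OLS fits of each endogenous score on its
direct parents (no intercept is needed on standardized scores). Total
effects accumulate path products over every directed route,
$A + A^2 + \dots$ on the coefficient matrix. A "location parameter" pair
(slope, intercept) per latent records the exact affine map from the
standardized score to the unstandardized 0–100 score used by IPMA, so the
two constructions can be cross-checked against each other.

## Evaluation statistics and decision rules

For a reflective block with loadings $\lambda_i$:

* $AVE = \sum\lambda_i^2 / (\sum\lambda_i^2 + \sum(1-\lambda_i^2))$, which
  simplifies to the mean squared loading; valid if $> 0.5$.
* $\rho_c = (\sum\lambda_i)^2 / ((\sum\lambda_i)^2 + \sum(1-\lambda_i^2))$;
  reliable if $> 0.7$. Cronbach's alpha is deliberately omitted: it
  assumes equally weighted indicators, which the weighting scheme
  contradicts, and $\rho_c$ is the appropriate statistic here.
* Indicator validity: loading strictly greater than 0.5 (a boundary value
  fails).
* Discriminant validity: cross-loadings (own-latent correlation must
  strictly exceed every other entry in the indicator's row — ties fail)
  and the Fornell–Larcker criterion ($\sqrt{AVE}$ strictly above the
  absolute score correlations in the latent's row).
* $R^2 = \sum_h \hat\beta_h\,\mathrm{corr}(parent_h, child)$, identical to
  the OLS coefficient of determination (asserted in the tests). Categories:
  weak below 0.33, moderate in $[0.33, 0.67)$, strong at or above 0.67 —
  boundary values go to the higher category.
* $GoF = \sqrt{\overline{AVE}\cdot\overline{R^2}}$ and
  $Q^2 = 1-\prod_j(1-R_j^2)$ (the composite form; omission-distance
  blindfolding is not implemented).

`gof()` takes explicit value vectors rather than hiding an averaging rule:
published analyses are not always explicit about which blocks enter the
mean AVE, and the two choices can differ materially. The assembled report
defaults to all reflective blocks' AVEs and all endogenous $R^2$ values.

Report tables round half-up to 3 decimals for display; full precision is
kept internally and in machine-readable exports.

## Bootstrap inference

Composite models make no distributional assumptions, so significance is
assessed by a nonparametric bootstrap: $B$ row-resamples with replacement
(default $B = 2000$), a full re-estimation on each, and
$se(\hat\theta^*) = $ the replicate standard deviation ($B-1$
denominator). Tests use $t = \hat\theta / se$ against a Student $t$ with
$n - 1$ degrees of freedom, $n$ the number of observations — exact $t$
quantiles always, although for $n > 30$ the familiar 1.96 cut-off is a
close approximation at $\alpha = 0.05$.

Two protocol details matter in practice:

* **Sign alignment.** A resample can flip a principal component's
  orientation, which would contaminate replicate spreads with sign noise.
  Each replicate latent is re-oriented when the dot product of its weight
  vector with the original-sample weight vector is negative; the flip
  propagates to the block's loadings and to each path coefficient touching
  the latent (standard practice for composite-model bootstrapping).
* **Failed resamples.** A resample on which the estimator degenerates
  (e.g. a zero-variance column) is discarded and counted; more than 10 %
  discards abort the run. The resample stream is consumed in a fixed
  order, so results are bit-reproducible given the seed (which is a
  required argument — there is no hidden global default).

Parameters with zero replicate spread (single-indicator loadings are
identically 1) are reported as non-testable rather than significant.

## Importance–performance analysis

IPMA answers "what should be improved first to move a target outcome".
Indicators are rescaled to $[0, 100]$ via
$x' = (x - \min)/(\max - \min)\cdot 100$, with empirical bounds by default
or user-supplied theoretical bounds (violations of theoretical bounds are
errors, not clipped). Rescaling is applied per observation; because the
map is affine, means of rescaled values equal rescaled means, so
performance is unaffected by that choice.

* **Performance** of an indicator is its mean rescaled value; a latent's
  performance is the block-weighted sum with *normalized unstandardized
  weights* (standardized weight divided by the indicator's rescaled-scale
  standard deviation, then block-normalized to sum to one). With
  non-negative weights this is a convex combination, hence stays in
  $[0, 100]$. Blocks whose weights have mixed signs cannot be normalized
  this way; that pathology is reported as an explicit error.
* **Importance** of a predecessor latent is its *unstandardized* total
  effect on the target, obtained by re-estimating the per-equation OLS on
  the 0–100-scale latent scores (with intercepts) and accumulating path
  products — not by ad-hoc standard-deviation ratios. Indicator importance
  is the normalized weight times the latent importance, so block indicator
  importances sum exactly to the latent importance (a tested invariant).
  Negative importances from negative total effects are retained with their
  sign; they mean "improving this lowers the target".
* **Quadrants.** The crosshair defaults to the mean importance and mean
  performance of the plotted items (a fixed crosshair can be supplied).
  Items on a crosshair line go to the high side ($\geq$ convention).
  Importance is plotted on the horizontal axis and performance on the
  vertical axis; `flip_axes` restores the classic presentation with
  importance vertical.

The pipeline (`run_pls_pipeline()`) optionally prunes weak indicators
before IPMA and refits. The rule implemented is: remove an indicator when
its loading fails the validity threshold **and** its bootstrap test is not
significant. Requiring both conditions keeps borderline indicators whose
loading is below the threshold but clearly non-zero — the behaviour
observed in applied practice — and the step is logged in the manifest and
can be disabled. Pruning may never empty a block; that is an error with an
actionable message.

## The synthetic-data generator

Every distributional claim in the test suite is checked against data with
*known* population structure, generated by following the model equations
literally: exogenous latents are standard normal; each endogenous latent
is the path-weighted sum of its parents plus a disturbance scaled so its
variance is exactly one (admissibility — positive disturbance variance —
is checked up front); indicators are $\lambda L + \sqrt{1-\lambda^2}\,e$.
Errors are Gaussian by default — the method is distribution-free, but
Gaussian errors make recovery tolerances analyzable — with a standardized
shifted-lognormal option to exercise skewness. Seeds are mandatory.

`default_sim_config()` is the package's reference population: five latents
with block sizes 3/1/1/7/3 (15 indicators), six paths — one exogenous
socioeconomic construct driving three mediators (parenting, food security,
health-and-environment services) that drive a malnutrition target — with
structural coefficients 0.464, 0.720, 0.513, −0.185, 0.178, −0.011,
population loadings 0.9 for multi-indicator blocks (1.0 for the
single-indicator blocks), and $n = 38$, a district-level cross-section.
This mirrors a realistic epidemiological design: one strong, one moderate
and one near-null mediated route, negative effects included.

What the generator does *not* emulate: spatial correlation between
districts, missing data, measurement scales with floor/ceiling effects, or
formative measurement. Passing recovery tests therefore demonstrates
correctness of the estimator under the stated model, not robustness to
those real-data features.

## Validation problem sizes

The suite checks, among others: weight/eigenvalue agreement with an
independent SVD oracle on 100 random blocks of up to 8 indicators
(discrepancy below $10^{-10}$); parameter recovery on the five-latent
design at $n = 5000$ over 20 seeds (median absolute error below 0.03 for
loadings, 0.05 for paths — the residual bias is the expected composite
attenuation); bootstrap type-I error within $[0.02, 0.09]$ and power
$\geq 0.95$ at a population path of 0.7, both at $n = 200$, $B = 500$,
200 Monte-Carlo repetitions; and 95 % percentile-interval coverage
$\geq 90\%$ over 40 repetitions at $n = 500$ with $B = 200$. These sizes
were chosen as the smallest designs at which the binomial/Monte-Carlo
noise is comfortably below the asserted margins.

## Known limitations

* Only recursive (acyclic) structural models; no higher-order constructs,
  moderation terms, or multigroup analysis.
* Formative blocks are specified but not evaluated (no formative
  outer-weight regression estimation, no consistent-PLS correction).
* $Q^2$ is the composite form, not blindfolding; no HTMT ratio; no
  Cronbach's alpha (see above).
* Bootstrap intervals are percentile-based for diagnostics; no BCa or
  studentized intervals, no jackknife or permutation tests.
* A latent score is defined up to sign; all reported quantities follow the
  orientation rule above, and cross-software comparisons should allow for
  per-latent sign flips.
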
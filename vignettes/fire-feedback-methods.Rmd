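---
title: "Methods: lagged-covariance fire feedback assessment and ensemble predictability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lagged-covariance fire feedback assessment and ensemble predictability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgefafire)
```

## The scientific problem

Regional fire activity (fire carbon emission, burned-area fraction) is a
fast variable: its month-to-month memory is short. The environmental
states that modulate it — sea-surface temperature (SST) modes, leaf area
index (LAI, a fuel-supply proxy), surface soil moisture — evolve slowly,
with red-noise memory of several months. This separation of timescales is
what makes two things possible at once:

1. **Attribution.** The instantaneous response of fire to each slowly
   evolving forcing can be identified from lagged covariances, even when
   the forcings are mutually correlated.
2. **Seasonal prediction.** Because the forcings persist, their past
   values carry usable information about fire months ahead, which a
   learner ensemble can convert into seasonal predictive skill.

`sgefafire` implements both halves against a synthetic generator whose
ground truth (response coefficients, memory, correlation structure,
noise level) is known exactly, so every statistical property of the
method can be verified rather than assumed.

## The feedback model and estimator

The response model is

$$F(t) = \mathbf{R}\,\mathbf{O}(t) + N(t),$$

where $F$ is the fire anomaly, $\mathbf{O}(t)$ the column of forcing
anomalies at month $t$, $\mathbf{R}$ the response vector (fire units per
forcing standard deviation), and $N$ short-memory internal noise.
Multiplying by $\mathbf{O}^\top(t-\tau)$ and taking covariances gives

$$\mathbf{C}_{F\mathbf{O}}(\tau) = \mathbf{R}\,\mathbf{C}_{\mathbf{OO}}(\tau)
  + \mathbf{C}_{N\mathbf{O}}(\tau).$$

A slowly evolving forcing cannot be driven by subsequent fire noise, so
$\mathbf{C}_{N\mathbf{O}}(\tau) \approx 0$ once the lag $\tau$ exceeds
the fire persistence time, and

$$\hat{\mathbf{R}} = \mathbf{C}_{F\mathbf{O}}(\tau)\,
  \mathbf{C}_{\mathbf{OO}}^{-1}(\tau).$$

`estimate_response()` is exactly this, with sample covariances
(denominator $n-1$) over pooled samples. The default lag is one month —
long enough for fire noise to decorrelate, short enough that the forcing
autocovariance $\mathbf{C}_{\mathbf{OO}}(\tau)$ remains well
conditioned. The generator applies its true responses at lag zero
(instantaneously), matching the model; a nonzero generative lag is
available for robustness experiments but is not a default condition.

Key numerical choices:

- $\mathbf{C}_{\mathbf{OO}}(\tau)$ is a *lagged* autocovariance and is
  not symmetric; it is inverted directly. If its condition number
  exceeds 1e8 a pseudo-inverse is substituted with a warning that
  recommends stepwise forcing reduction — shrinking the forcing set is
  the intended cure for ill-conditioning, not ridge-style regularization
  that would bias $\hat{\mathbf{R}}$.
- Seasonal estimates pool the three months of each overlapping 3-month
  season across all years (season 1 = Jan–Mar, …, season 12 = Dec–Feb),
  so a 20-year record gives up to 60 samples per season; the pooled
  triples are $(F(t), \mathbf{O}(t), \mathbf{O}(t-\tau))$, and pairs
  whose lagged month precedes the record are dropped and counted (the
  seasons containing the first January lose exactly one).

## Forcing selection by backward-stepwise AIC

With 18 candidate forcings and 60 pooled samples per season, the full
estimator is noisy; unimportant forcings are dropped to minimize
sampling error. `backward_stepwise()` starts from the full matrix and
repeatedly removes the forcing whose removal most decreases

$$\mathrm{AIC} = n\,\ln(\mathrm{RSS}/n) + 2k,$$

the Gaussian concentrated-likelihood form with $k$ = number of forcings
+ 1 (the noise variance). **The residual sum of squares is taken against
the contemporaneous forcings**, $\mathrm{RSS} = \sum_t (F(t) -
\hat{\mathbf{R}}_S\,\mathbf{O}_S(t))^2$: the model being scored is the
instantaneous response model, and the lag enters only through the
estimation of $\hat{\mathbf{R}}$. This matters. The coefficient
$\hat{R}_j$ is *not* the least-squares coefficient of the lagged
forcing; scoring the fit against $\mathbf{O}(t-\tau)$ would overweight
every forcing by $1/\phi_j$ (its lag-$\tau$ autocorrelation) and
systematically eject true low-memory forcings — in simulation, support
recovery under the reference conditions drops from 1.00 to 0.70 if the
lagged residual is used. Ties between removals (equal AIC gain within
1e-9) are broken deterministically by removing the forcing with the
smallest $|\hat{R}|/\mathrm{SE}$ under an analytic (permutation-free)
standard error.

Selection stops when no removal decreases the AIC; the final response
vector is re-estimated on the retained subset. Forcings that were
dropped are reported as *absent* (NA), never as zero — an estimate of
zero is a statement, absence is not.

## Permutation significance

Significance of each retained response is assessed with a Monte-Carlo
permutation test (`bootstrap_significance()`, 1000 iterations by
default): the pooled fire sample vector is randomly permuted, the
response re-estimated, and the two-sided p-value is the fraction of
permuted $|\hat R_j^\ast|$ at least as large as observed, with a
$+1/(n_{\mathrm{iter}}+1)$ continuity correction so p is never exactly
zero. Permuting $F$ preserves its marginal distribution exactly (the
permutation is a bijection on the sample multiset) while destroying any
lagged relationship; because the pooled fire samples are separated by a
month or more and fire memory is short relative to $\tau$, exchangeability
under the null is a good approximation. For strongly autocorrelated fire
samples a block-permutation variant (`block =` length) preserves
short-range memory under the null. Significance is declared at p < 0.1
(90% confidence), two-sided. Under null simulations the empirical
rejection rate at this level is 0.08–0.10, consistent with nominal.

Summaries mirror the assessment products: `seasonal_feedback_cycle()`
runs selection and significance independently per season (no smoothing
across overlapping seasons), `max_response_season()` reports the season
of maximum absolute *significant* response per forcing,
`robustness_count()` counts significant responses across dataset
combinations, and `spatial_response_map()` applies the estimator
per grid cell, masking insignificant cells.

## The prediction system

`ensemble_predictability()` implements the repeated-random-split
protocol:

- **Splits.** Year-block mode holds out one quarter of the calendar
  years (5 of 20) so no year contributes to both sides; an all-season
  table then tests on ~60 monthly anomalies and a season-specific table
  on ~15. Month-random mode (180/60 months) is available as the
  robustness variant.
- **Learners.** Five families behind one contract: random forest
  (`ranger`), support-vector regression (`e1071`), a single-hidden-layer
  feed-forward network (`nnet`), an L1-penalized linear model
  (`glmnet`), and gradient-boosted trees (`xgboost`). Hyperparameters
  come from small fixed grids (documented in `learner_grid()`) chosen by
  10-fold cross-validation minimizing RMSE on the training part only;
  predictors are standardized with training statistics only. Everything
  is deterministic given the member seed.
- **Scoring.** Skill is the squared Pearson correlation between observed
  and predicted test values. By that definition an anti-correlated
  prediction also scores 1; this is accepted as the protocol's
  documented semantics. Members whose predictions are constant
  (undefined correlation) are recorded as 0 and counted.
- **Best learner.** Chosen once, by highest ensemble-mean $R^2$ across
  the 100 members — never per member, which would leak selection
  optimism into the reported distribution. The reported predictability
  is the best family's ensemble mean with its 10th/90th percentile
  member range. Per-member selection remains available for comparison
  via the stored member-by-learner matrix.

Predictor tables (`build_predictor_table()`) give every environmental
predictor three lagged copies at leads $L, L{+}1, L{+}2$ months —
extending the one-to-three-months-ahead convention to longer leads — so
no environmental column uses information later than $t - L$.
Socioeconomic predictors enter as a single step series carrying the
value reported at the end of the target month's antecedent calendar
year; this follows the reporting-cadence rule even at long leads, where
for early-calendar-year targets the antecedent-year report may postdate
the environmental information cutoff by a few months. That is a
deliberate reading of the cadence convention, not an oversight, and it
affects only the slow annual series.

## The synthetic generator

`simulate_bundle()` produces the study conditions the tests assume:

- **Forcings.** 18 zero-mean, unit-variance AR(1) series (16 basin SST
  principal components + LAI + soil moisture) with lag-1
  autocorrelation 0.8 by default (0.6–0.9 in the stress conditions) and
  exchangeable cross-correlation 0.2 (up to 0.5 supported). Cross
  correlation is induced through a Cholesky factor of an innovation
  covariance that is *memory-adjusted*: the innovation correlation is
  scaled by $(1-\phi_i\phi_j)/\sqrt{(1-\phi_i^2)(1-\phi_j^2)}$ so the
  *stationary* cross-correlations equal the target exactly even when
  memories differ. The unadjusted construction misses the target by up
  to ~30% at these memory levels; the adjusted innovation matrix is
  checked for positive semidefiniteness and refused otherwise.
- **SST fields.** Each basin's field is two prescribed spatial modes
  (orthonormal under cos-latitude area weights) times the basin's two
  PC truth series, plus spatially white noise, a seasonal cycle, and a
  linear trend; mode 1's amplitude strictly exceeds mode 2's so the EOF
  ordering is identified.
- **Fire.** The fire anomaly is exactly
  $\mathbf{R}_{\mathrm{true}}\,\mathbf{O}_{\mathrm{std}}(t)$ plus
  i.i.d. Gaussian noise; white noise is the minimal choice consistent
  with the identifying assumption that noise memory is much shorter
  than $\tau$. Default truth: three nonzero responses — tropical
  Pacific PC1 +0.8 (warm-phase enhancement), LAI +0.5 (fuel supply),
  soil moisture −0.6 (wet soils inhibit burning) — with unit noise, a
  20-year record (240 months) matching a typical satellite fire-record
  length.
- **Predictors.** Atmospheric series with configurable correlation to
  the fire anomaly; annual socioeconomic random walks expanded by the
  antecedent-year rule.

What the generator does **not** emulate: realistic geography or
land/ocean masks, satellite retrieval error, nonlinear or threshold
fire responses, non-Gaussian noise, or the observational datasets'
actual spectra. Passing tests therefore demonstrate the statistical
correctness and calibration of the machinery under its stated
assumptions — not that any particular real-world response value is
reproduced.

## EOF conventions

Basin SST anomaly fields are decomposed by SVD of the
$\sqrt{\cos\varphi}$-weighted data matrix, making explained variance
area-true. Patterns are returned in native units, orthonormal under the
area weights; PC series are mutually uncorrelated. EOFs are computed
once per basin over the full record (one forcing matrix feeds all
seasonal selections), and the leading-two PCs are standardized to unit
variance with the divisor $\sigma_{\mathrm{forcing}}$ retained so
responses can be converted back to native units. Sign is fixed by
making each pattern's area-weighted spatial mean non-negative (pattern
and PC flip together, leaving every reconstruction and every $|R|$
unchanged). Standardized PCs are the default forcings; raw PCs remain
available (`standardized = FALSE`).

## Design choices that were genuinely open

- **Detrending order.** Monthly anomalies first, then a linear detrend,
  applied per cell for fields and per series for regional means; the
  alternative order changes nothing detectable for linear trends, and
  this order keeps the climatology interpretable.
- **Pooling for the seasonal estimator** uses triples
  $(F(t), \mathbf{O}(t), \mathbf{O}(t-\tau))$ because the lagged
  forcing autocovariance genuinely requires the forcings at both times.
- **AIC residuals against contemporaneous forcings** (see above): the
  alternative demonstrably breaks selection consistency.
- **Stepwise before significance.** Selection runs first; the
  permutation test is applied to the retained subset. Running
  significance first would test 18 coefficients estimated jointly from
  60 samples — exactly the sampling-error regime selection exists to
  avoid.
- **Six-combination robustness counting** takes an arbitrary list of
  estimates, since the composition of dataset combinations is an input,
  not a constant of the method.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script experiments run at deliberately
moderate sizes chosen to keep every check's Monte-Carlo error well
inside its decision margin: 50–100 replicates for support recovery and
calibration (null rejection pooled over 200–600 decisions), 20–50
replicates per record length for consistency, 25-member ensembles with
all five learner families for the skill ceiling, and 5–10 members with
the faster learner subsets for the ordering and lead-decay properties,
which compare means across conditions rather than absolute levels.
Ensemble sizes and learner subsets for those property checks are stated
in the tests themselves.

## Known limitations

- The estimator is linear; a forcing whose true influence is purely
  nonlinear will be attributed only through its linear projection (the
  learner ensemble, by contrast, can exploit it).
- Permutation significance assumes the pooled fire samples are
  exchangeable under the null; block permutation mitigates but does not
  remove sensitivity to strong fire-side autocorrelation.
- The skill metric (squared correlation) ignores bias and amplitude
  errors in predictions.
- Year-block splits at 20 years give only $\binom{20}{5}$ distinct
  splits; ensemble percentiles at 100 members are therefore modestly
  discretized.
- `spatial_response_map()` runs the permutation test independently per
  cell with no multiplicity control; the expected false-unmasked
  fraction under the null is the nominal level $\alpha$.
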
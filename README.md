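# sgefafire

Seasonal drivers and predictability of regional fire activity, in two
connected halves:

1. **Feedback assessment.** The stepwise Generalized Equilibrium
   Feedback Assessment (SGEFA): a lagged-covariance estimator of the
   instantaneous response of a fast ecological variable (monthly fire
   carbon emission or burned-area fraction) to slowly evolving oceanic
   and terrestrial forcings — basin SST principal components, leaf area
   index (LAI), surface soil moisture. Writing the response model as
   *F(t) = R O(t) + N(t)* and using the fact that slow forcings cannot
   be driven by subsequent fire noise (*C\_NO(τ) ≈ 0* for a lag τ longer
   than the fire persistence time), the response vector is identified as

   **R** = **C**\_FO(τ) · **C**\_OO(τ)⁻¹

   with τ = 1 month, backward-stepwise AIC selection of the forcing
   subset, and Monte-Carlo permutation significance (1000 iterations,
   p < 0.1, two-sided), run independently for each overlapping 3-month
   season.

2. **Prediction.** A seasonal fire prediction system from five
   machine-learning families (random forest, support-vector regression,
   feed-forward neural network, L1-penalized regression, gradient
   boosting) behind one contract: lagged predictor tables (environmental
   predictors at leads L…L+2 months, socioeconomic predictors at
   antecedent-year cadence), repeated random 15-yr/5-yr (or
   180/60-month) train/test splits, 10-fold CV hyperparameter tuning
   minimizing RMSE, and a 100-member ensemble whose best family —
   selected on ensemble-mean R² — defines the reported predictability
   with its 10th/90th percentile range.

Everything is exercised end to end on a synthetic-data generator with
known feedback coefficients (correlated AR(1) forcings, rank-2-plus-noise
basin SST fields, a fire series that satisfies the response model
exactly before noise), so support recovery, estimator consistency, test
calibration, and predictability ceilings are verified against ground
truth. The intended audience is researchers in fire ecology and
climate–ecosystem statistics who need a tested reference implementation
of the lagged-covariance attribution + learner-ensemble prediction
workflow.

## Worked example

```r
library(sgefafire)

# a 20-year synthetic study: 18 forcings, three true responses
# (TP-PC1 = +0.8, LAI = +0.5, SM = -0.6), unit fire noise
cfg    <- synth_config(seed = 3)
bundle <- simulate_bundle(cfg)

# preprocess: monthly anomalies, linear detrend; EOF forcing matrix
fire <- detrend_linear(monthly_anomalies(bundle$fire))
O    <- build_forcing_matrix(bundle)   # 16 basin PCs + LAI + SM

# full-record stepwise feedback assessment
est <- sgefa_fit(fire, O, season = NULL, n_iter = 1000, seed = 1)
est
#> <feedback_estimate: full record, tau=1, n=239, 5/18 retained, 3 significant (p<0.1)>
#>  forcing       R      p
#>   TP-PC1  0.5387 0.0010
#>   TI-PC2  0.0656 0.6204
#>   NP-PC2  0.0524 0.7143
#>      LAI  0.3303 0.0130
#>       SM -0.4765 0.0010
```

The three generatively active forcings — tropical-Pacific PC1, LAI and
soil moisture — are retained and significant with the correct signs
(responses are in fire-anomaly units per forcing standard deviation;
the TP-PC1 value is attenuated relative to its truth of 0.8 because the
EOF-estimated PC is a noisy version of the generating series); the two
incidentally retained forcings are correctly declared insignificant.
`seasonal_feedback_cycle()` repeats this per 3-month season, and
`max_response_season()` / `robustness_count()` summarize the cycle.

Prediction from the same bundle:

```r
pool <- predictor_pool(bundle)
tab  <- build_predictor_table(pool, lead = 1, set = "ocean_land")
res  <- ensemble_predictability(tab, n_members = 100, seed = 1)
res
#> <forecast_result: set=ocean_land lead=1, best=lasso, mean R2=0.084 [0.012, 0.165], 100 members>
```

One-month-ahead skill on this particular 20-year realization is modest,
and honestly so: the attainable linear skill of a lagged predictor is
the signal fraction of fire variance times the squared one-month forcing
memory, further attenuated by EOF estimation of the forcings, and a
240-month record realizes that share with wide sampling variability
(this bundle's lag-1 oracle skill is R² ≈ 0.15). The calibrated-skill
demonstration — a generator with a theoretical R² ceiling of 0.5, where
the ensemble recovers ≈ 0.44 — is run by the acceptance script below.
`compare_predictor_sets()` runs the full grid of predictor sets × leads ×
model modes, and `importance_scores()` gives permutation importances for
the best family.

Pipeline drivers (`cmd_simulate`, `cmd_sgefa`, `cmd_forecast`,
`cmd_report`) run the same stages from a YAML configuration and write
deterministic CSV/markdown outputs.

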
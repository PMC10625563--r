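# pairmnar

Two-stage analysis of longitudinal outcomes whose self-reporting process
may depend on the outcome itself — the *missing not at random* (MNAR)
regime that daily self-weighing studies live in: participants tend to skip
the scale precisely on the days they expect a disappointing number, and any
method that treats the reporting times as uninformative (complete-case
least squares, GEE) is then biased.

The package is aimed at biostatisticians analysing longitudinal
self-reported outcomes (daily weights from connected scales, app-based
diaries, patient-reported outcomes) where the observation-time process is
plausibly outcome-dependent and too messy to model.

## What it implements

**Stage I — a semiparametric test of the missing-data mechanism.** For a
cross-sectional summary per subject (milestone-day outcome or subject
mean), two estimators of the same GLM coefficient vector are contrasted:
the complete-case maximum-likelihood estimator β̂ of the exponential
dispersion family working model, and a pairwise pseudo-likelihood estimator
β̃ whose slope maximises

    Σ_{i<i'} −log(1 + exp(−(β₁ᵀ(x_i − x_i'))(y_i − y_i')))

in which the baseline response density — and any outcome-only selection
factor — cancels. Under MCAR or MAR-on-covariates both are consistent for
the same natural-parameter coefficients; outcome-dependent selection moves
the MLE. The statistic

    T = n (β̃ − β̂)ᵀ Ŵ⁺ (β̃ − β̂),

with Ŵ the covariance of the difference of the two estimators' influence
functions, is referred to the χ² law with df equal to the rank the contrast
carries; large T is evidence of MNAR.

**Stage II — a pairwise composite conditional likelihood estimator.** Under
the density-ratio model f(y|x) ∝ exp(βᵀx·y)·g(y) with unspecified base g,
conditioning a cross-subject pair of observations on its order statistics
cancels g, leaving

    P(assignment | order stats) = 1 / (1 + exp(−(βᵀ(x₁−x₂))(y₁−y₂))).

The composite log likelihood sums this over all cross-subject observation
pairs (subjects with K_i and K_i' reports contribute K_i·K_i' pairs); it is
globally concave, maximised by Newton iteration, with subject-clustered
Godambe (sandwich) standard errors. Because g absorbs any outcome-only
reporting factor, the estimator is consistent under product-form MNAR —
no model of the self-reporting process is ever fit. Coefficients are on
the density-ratio (tilt) scale: mean-scale effects divided by the outcome
variance for Gaussian outcomes.

A synthetic-cohort generator emulates a three-arm daily-weighing trial
(~190 subjects, arms 1:2:2 control / direct payment / lottery, outcome =
daily weight − baseline weight in lb) with MCAR / MAR / product-form MNAR
selection, and a Monte-Carlo harness measures size, power, bias, RMSE and
coverage.

## Worked example

Simulate a trial-like cohort whose reporting odds fall with the day's
weight change, more steeply for older participants (a non-separable
selection mechanism), then run both stages:

```r
library(pairmnar)

mech <- missingness_mechanism("mnar_interaction",
                              x_coefs = c(1.5, 0, 0.3, 0),
                              y_coefs = c(0.8, -0.3), xy_coef = 0.2)
cfg <- simulation_config(
  n_subjects = 189, schedule_length = 30,
  true_beta = c(sex = -1, baseline_bmi = 0, age = 0.05, time = -3,
                "lottery:time" = -1.5, "direct_payment:time" = -1),
  noise_sd = 5, mechanism = mech, seed = 11)
cohort <- simulate_cohort(cfg)

report <- run_pipeline(cohort, pipeline_config(summary = "milestone_day",
                                               milestone_day = 15))
report
```

```
Two-stage analysis of outcome-dependent missingness
Missing daily reports by arm (%):
       control direct_payment        lottery
          27.3           27.0           31.1

-- Stage I: mechanism test --
Semiparametric test of the missing-data mechanism
  T = 9.205 on df = 2, p-value = 0.01003 (n complete = 136)
                      (Intercept)    age     sex
MLE (beta-hat)             0.0049 0.0132 -0.1063
Pairwise (beta-tilde)      0.0257 0.0169 -0.1218
  Large T: evidence the outcome is missing not at random.
  Verdict: evidence of MNAR (T = 9.205, df = 2, p = 0.01003 < 0.05)

-- Stage II: pairwise composite likelihood --
Pairwise composite conditional likelihood fit
  8122082 observation pairs, log composite likelihood -4375772.4201, 6 Newton iterations
                    Effect size     SE       z p-value
sex                     -0.0244 0.0161 -1.5117  0.1306
baseline_bmi             0.0013 0.0014  0.9839  0.3252
age                      0.0188 0.0010 18.2809  0.0000
time                    -0.1315 0.0226 -5.8243  0.0000
lottery:time            -0.0536 0.0267 -2.0043  0.0450
direct_payment:time     -0.0292 0.0258 -1.1335  0.2570
  (coefficients on the density-ratio/tilt scale; divide mean-scale
  effects by the outcome variance to compare)
```

Reading it: Stage I rejects ignorable missingness (T = 9.21 on 2 df,
p = 0.01) — the generator made reporting depend jointly on age and the
day's weight change. The Stage-II effects are on the tilt scale (here
mean-scale / 25, since noise_sd = 5): `time` = −0.132 recovers the
generated −3 lb/month ÷ 25 = −0.12, and both incentive-by-time
interactions are negative (incentive arms maintain weight loss better over
time than control), with the lottery interaction the larger — despite over
a quarter of daily reports missing in an outcome-dependent way. One honest
blemish is visible by design: the `age` coefficient (0.019 vs a generated
0.002) absorbs the age-by-outcome interaction in the selection process,
because non-separable selection violates the pairwise method's product-form
assumption for that covariate; under exactly product-form selection all
coefficients are recovered (that case is what the test suite verifies), and
the time-effect contrasts here remain close to truth regardless.

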
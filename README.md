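# frscal

Transport, recalibration, refitting and validation of sex-specific
Framingham-type coronary heart disease (CHD) risk equations, aimed at
biostatisticians and epidemiologists who need to ask: *does an external
risk score still work in my (older) cohort, and if not, can it be fixed
without re-deriving it?*

Risk equations developed in middle-aged populations are routinely applied
to adults in their seventies, where both the baseline hazard and the
risk-factor distribution differ. `frscal` implements the standard
three-way comparison on a person-level censored cohort:

1. **Original equation** — predicted risk
   `p = 1 − S0(t)^exp(L − L̄)`, with linear predictor
   `L = Σ βj xj` over categorized risk factors (NCEP cholesterol bins,
   JNC blood-pressure stages, diabetes, current smoking, age and age² for
   women), reference means `x̄j`, and the published 10-year baseline
   survival rescaled to any horizon t under an exponential model,
   `S0(t) = S0(10)^(t/10)`.
2. **Recalibrated equation** — identical coefficients, but the cohort's
   own risk-factor means and its Kaplan-Meier survival at t as baseline.
   A strictly monotone transform of the original score: absolute risks
   change, ranking (Harrell's C) provably cannot.
3. **Refit equation** — a Cox proportional-hazards model re-estimated on
   the cohort with data-driven category pooling, its baseline survival
   evaluated at the covariate means.

Each variant is scored per person and evaluated for **discrimination**
(Harrell's C with censored-data pair conventions, bootstrap optimism
correction, bootstrap C comparison) and **calibration** (a decile-based
chi-square adapted to censored data via within-decile Kaplan-Meier
estimates, plus predicted/observed ratio tables). A synthetic
elderly-cohort generator with a known proportional-hazards event process
makes the entire pipeline testable against ground truth; a
proportional-hazards diagnostic (Schoenfeld-residual score test) and the
exploratory predictor-selection procedures (p < 0.20 screen, backward
p < 0.10, forward stepwise AIC/BIC) round out the toolkit.

## Worked example

Score, recalibrate and refit a synthetic cohort of 2193 older adults
(55% women) whose event process has a several-fold higher baseline hazard
than the original women's equation implies:

```r
library(frscal)
library(dplyr)

cohort <- generate_cohort(cohort_spec(n = 2193), seed = 42) |>
  apply_exclusions()
women <- filter(cohort, sex == "female")

frs   <- frs_score(women, horizon = 7.5)                      # original
recal <- frs_score(women, recalibrate(frs_coefficients("female"), women))
fit   <- fit_cox(women, habc_terms("female"))                 # refit
refit <- refit_risk(fit, women, horizon = 7.5)

harrell_c(frs)$c_index                  # 0.674 (identical for recal)
glance(hl_cox(frs))[1:3]                # chi-sq 60.2, df 9, p = 1.2e-9
glance(hl_cox(recal))[1:3]              # chi-sq 10.8, df 9, p = 0.29
glance(hl_cox(refit))[1:3]              # chi-sq  8.2, df 9, p = 0.51
decile_ratio(frs) |> tail(1)            # overall predicted/observed = 0.56
```

Read: the original equation ranks women acceptably (C = 0.674) but
predicts only 56% of the risk actually observed — it fails the
calibration test decisively (p ≈ 1e-9). Keeping its coefficients and
substituting the cohort's means and Kaplan-Meier baseline
(`recalibrate()`) repairs absolute risk (p = 0.29) without moving C;
refitting the coefficients (`fit_cox()` + `refit_risk()`) calibrates as
well (p = 0.51) with a marginally better C. `hazard_ratios(fit)`,
`ph_test(fit)`, `tidy()`, `glance()` and `autoplot()` give the usual
inspection surfaces, and `as_coefficient_set(fit)` exports the refit as a
portable JSON risk equation.

Note: the bundled coefficient file carries the published equation
coefficients and baseline survivals, but *synthetic* stand-in reference
means (the development cohort's means are not redistributed); supply your
own via `read_coefficient_set()` for production scoring.

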
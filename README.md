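# inrsteady

Predict **when** a warfarin patient's INR will reach steady state and
**what** that steady-state INR will be, from two timed blood samples in
which INR and plasma factor VII activity are measured together.

## The problem

After a warfarin dose change, the INR keeps drifting for two to four
weeks because the vitamin K-dependent clotting factors decay at very
different rates: factor VII has a half-life of about 6 hours, factor II
of days. An INR drawn on day 3 or 4 therefore under-states the eventual
response, and dose titration by trial and error is slow and risks
over-anticoagulation. `inrsteady` implements an empirical model-order
reduction of a mechanistic coagulation model that turns two early paired
INR/factor VII measurements into a forecast of the time to steady-state
INR and its value.

## The model in brief

With factor VII in percent of its pre-treatment baseline, the INR
sensitivity index is approximated by `SI(t) ≈ q · INR(t) / VII(t)`
(`q = 0.233`). Its rate of change declines as a logistic in time,

```
dSI/dt = h / (1 + exp(p (t − g)))
h = a0 + a1·D_ref        g = b0 + b1·ln(D_ref)        p = 0.300 /day
```

where `D_ref` is the *reference dose* — the daily dose a typical patient
would need to match this patient's response. Two paired samples give a
finite-difference estimate of `dSI/dt`; inverting the logistic family
for `D_ref` individualises the model. Steady state is declared when the
slope falls below `ε = 1.5e-4 /day`, giving a closed form for
`t_SS,INR`, and the INR accumulates through a quadratic map
`dINR/dt = k·(dSI/dt)² + m·(dSI/dt)` whose integrals over
`[0, t_SS]` are also closed-form, giving `INR_SS`. All constants are
published values, collected in `published_parameters()` and overridable
(including via YAML/JSON files).

For typical patients the model predicts, for example, `t_SS,INR` of
15.6, 19.5, 22.3 and 24.5 days and `INR_SS` of 2.29, 3.09, 3.90 and 4.68
at reference doses of 3.97, 6.78, 9.90 and 13.3 mg/day — time to
steady-state INR *increases* with dose, a counterintuitive but
mechanistically grounded prediction.

## Worked example

A patient on 5 mg/day is sampled on days 3 and 4 after the dose change:

```r
library(inrsteady)

samples <- tibble::tibble(
  patient_id     = "pt-01",
  time_days      = c(3, 4),
  inr            = c(1.86, 2.06),
  factor_vii_pct = c(44.2, 39.5)
)

pred <- predict_steady_state(samples, dose = 5)
pred
#> # A tibble: 1 × 9
#>   patient_id   si_t1  si_t2   slope  dref sensitivity_ratio t_ss_inr inr_ss
#>   <chr>        <dbl>  <dbl>   <dbl> <dbl>             <dbl>    <dbl>  <dbl>
#> 1 pt-01      0.00980 0.0122 0.00235  3.71             0.743     15.1   2.21
#> # ℹ 1 more variable: warnings <list>
```

The patient responds like a typical 3.71 mg/day patient despite taking
5 mg/day (sensitivity ratio 0.74, i.e. warfarin-resistant): the INR will
plateau around 2.21 after roughly 15 days. To reach a target INR of 2.5
instead:

```r
dose_for_target_inr(2.5, sensitivity_ratio = pred$sensitivity_ratio)
#> [1] 6.254426
```

`tidy()` and `glance()` give per-patient and cohort summaries;
`autoplot(pred)` draws the predictions. Batch input comes from CSV via
`read_samples()`, and `write_prediction_report()` emits a JSON report;
the same workflow is scriptable through `inst/cli/inrsteady.R`
(`predict`, `simulate`, `calibrate`, `fixtures` subcommands).

Synthetic patients with known ground truth are built with
`synthetic_patient()` + `simulate_time_course()` /
`make_paired_samples()`, and the calibration machinery
(`fit_q()`, `fit_logistic_family()`, `fit_quadratic_family()`) recovers
the published constants from such time courses.

See the vignette (`vignettes/steady-state-prediction.Rmd`) for the full
model, parameter table, numerical choices and limitations.

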
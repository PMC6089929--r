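---
title: "Predicting steady-state INR from paired factor VII and INR measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting steady-state INR from paired factor VII and INR measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inrsteady)
library(dplyr)
```

## The problem

Warfarin dosing is guided by the INR, but the INR observed during the
first days of therapy is not the INR the patient will settle at: the
vitamin K-dependent clotting factors decay at very different rates
(factor VII with a half-life of about 6 hours, factor II over days), so
the INR keeps drifting for two to four weeks. Clinicians therefore face
two questions early in therapy: *when* will this patient's INR be at
steady state, and *what* will it be?

`inrsteady` answers both from two timed blood samples in which INR and
factor VII are measured together, typically on days 3 and 4 after the
dose change — once factor VII itself has equilibrated, but long before
the INR has.

## The model

The sensitivity of the INR to factor VII is quantified by the
sensitivity index, the magnitude of the partial derivative of INR with
respect to factor VII. Because factor VII reaches its own steady state
quickly, the index can be approximated from a single paired measurement
by a proportional model,

$$SI(t) \approx q \,\frac{INR(t)}{VII(t)}, \qquad q = 0.233,$$

with factor VII expressed as percent of the pre-treatment baseline. Two
paired samples then give a finite-difference estimate of the index's
rate of change, $dSI/dt$.

That rate declines over time following a three-parameter logistic,

$$\frac{dSI}{dt} = \frac{h}{1 + e^{p (t - g)}},$$

whose asymptote and shift depend on the *reference dose* $D_{ref}$ — the
daily dose a typical patient would need to produce the same
anticoagulant response:

$$h(D_{ref}) = a_0 + a_1 D_{ref}, \qquad
  g(D_{ref}) = b_0 + b_1 \ln D_{ref},$$

with $p = 0.300\,\mathrm{d^{-1}}$ fixed, $a_0 = 3.92\times10^{-4}$,
$a_1 = 1.08\times10^{-3}$, $b_0 = -1.48$ d, $b_1 = 4.13$ d. Equating the
observed slope to this family and solving for $D_{ref}$ individualises
the model: a patient who needs only 5 mg/day to respond like a typical
10 mg/day patient is warfarin-sensitive ($D_{ref}/D = 2$).

Steady-state INR is declared when the slope falls to a tolerance
$\varepsilon = 1.50\times10^{-4}\,\mathrm{d^{-1}}$, which gives the
closed form

$$t_{SS,INR} = g(D_{ref}) + \frac{1}{p}
  \ln\!\left(\frac{h(D_{ref})}{\varepsilon} - 1\right),$$

clamped at zero if the tolerance is already met. The INR itself
accumulates according to a no-intercept quadratic map from the
sensitivity-index slope to the INR slope,

$$\frac{dINR}{dt} = k(D_{ref})\left(\frac{dSI}{dt}\right)^2
  + m(D_{ref})\,\frac{dSI}{dt}, \qquad
  k = -e^{c_0 + c_1 \ln D_{ref}}, \quad m = e^{s_0 + s_1 \ln D_{ref}},$$

with $c_0 = 11.9$, $c_1 = -2.05$, $s_0 = 5.26$, $s_1 = -0.672$, so that

$$INR_{SS} = INR_0 + k \int_0^{t_{SS}}\left(\frac{dSI}{dt}\right)^2 dt
  + m \int_0^{t_{SS}} \frac{dSI}{dt}\, dt.$$

Both integrals of the logistic have closed forms. With
$u = p\,(t - g)$,

$$\int \frac{h}{1+e^{u}}\,dt
  = h\left[t - \tfrac{1}{p}\ln(1+e^{u})\right], \qquad
\int \left(\frac{h}{1+e^{u}}\right)^2 dt
  = \frac{h^2}{p}\left[u - \ln(1+e^{u}) + \frac{1}{1+e^{u}}\right].$$

The second antiderivative is easy to verify by differentiation: its
derivative with respect to $u$ is $\sigma(-u)^2$ where $\sigma$ is the
logistic function. Both are evaluated in overflow-safe form (see
*Numerical choices*) and are tested against adaptive quadrature to
better than $10^{-8}$ relative error.

## The 4-step predictor

`predict_steady_state()` composes the steps per patient:

1. sensitivity indices at the two sample times (`approx_si()`),
2. their finite-difference slope (`slope_from_pair()`),
3. inversion of the logistic family for $D_{ref}$ (`invert_dref()`),
4. the closed forms for $t_{SS,INR}$ and $INR_{SS}$
   (`time_to_steady_state()`, `steady_state_inr()`).

```{r predict}
pt <- synthetic_patient(dref_true = 6.1)
samples <- make_paired_samples(pt)$samples
samples
predict_steady_state(samples, dose = 5) |> tidy()
```

## Tunable parameters

All constants live in a `published_parameters()` object and can be
overridden individually (and round-tripped through YAML/JSON files);
they are validated against the model's invariants before use.

| parameter | meaning | unit | default |
|---|---|---|---|
| `q` | SI proportionality constant | — | 0.233 |
| `p` | logistic shape | /day | 0.300 |
| `a0`, `a1` | asymptote intercept, dose slope | /%/day, /%/mg | 3.92e-4, 1.08e-3 |
| `b0`, `b1` | shift intercept, log-dose slope | days | −1.48, 4.13 |
| `c0`, `c1` | log-scale coefficients of `k` | — | 11.9, −2.05 |
| `s0`, `s1` | log-scale coefficients of `m` | — | 5.26, −0.672 |
| `eps_si` | steady-state tolerance on dSI/dt | /day | 1.5e-4 |
| `vii_equilibration_days` | earliest valid sample time | days | 2.0 |
| `dref_support` | supported reference doses | mg/day | [1, 13] |
| `inr_support` | supported INR range | — | [1.4, 4.7] |

The tolerance `eps_si` was selected in the source system by an ROC
analysis against a mechanistic coagulation model; it is treated here as
a published constant with a configuration override, and the selection
procedure is not re-implemented.

## Validity guards

The empirical system was developed for doses of 1–13 mg/day and INR
1.4–4.7, and the proportional sensitivity-index approximation does not
hold while factor VII is still equilibrating. Accordingly:

* samples earlier than 2 days after the dose change are a hard error
  (configurable threshold);
* a non-positive observed slope is a hard error — the patient is already
  at or beyond steady state, or the measurements are inconsistent, and
  the shift $g(D_{ref})$ is undefined for non-positive doses;
* a reference dose or predicted INR outside the supported ranges yields
  a structured *warning* (in the `warnings` column of the result), not
  an error — extrapolation is reported, not silently accepted;
* time is measured in days since the most recent dose-rate change;
  records spanning multiple dose rates are not supported and must be
  split at the last change.

## Numerical choices

* $\ln(1+e^{x})$ is evaluated on the standard stable branch
  ($x + \ln(1+e^{-x})$ for $x > 0$), and the squared-logistic
  antiderivative is rewritten for $u \ge 0$ in terms of $x = e^{-u}$ as
  $x/(1+x) - \ln(1+x)$; the naive form loses all precision in the far
  tail where the antiderivative behaves as $-x^2/2$. Evaluation is
  finite for $|p(t-g)|$ well past 700.
* $D_{ref}$ inversion equates the observed finite-difference slope to
  the *interval mean* of the logistic over $[t_1, t_2]$, i.e.
  $\int_{t_1}^{t_2} (dSI/dt)\,dt / (t_2 - t_1)$, rather than the
  midpoint value. A finite difference of the index *is* the interval
  mean of its derivative, so the noiseless round trip is exact under
  this convention; the midpoint variant is available via
  `mode = "midpoint"`. Which convention produced the originally
  reported per-patient reference doses is not determinable from the
  printed values alone; both reproduce them to within rounding.
* Root searches (`invert_dref()`, `dose_for_target_inr()`) use
  bracketed Brent iteration (`stats::uniroot`) to an absolute tolerance
  of 1e-10 on a fixed dose bracket of (0.01, 50] mg/day; the
  interval-mean slope is strictly increasing in the reference dose over
  that bracket for sampling windows in the validity region (checked by a
  property test on a grid), so the root is unique.
* $t_{SS,INR}$ is clamped at 0 when the tolerance is met at $t = 0$.
* Baseline INR defaults to 1.0 when unmeasured; predicted
  $INR_{SS} - INR_0$ is independent of the baseline.

## Calibration machinery

The empirical constants were originally obtained by model-order
reduction: simple functions fitted to the simulated behaviour of a
mechanistic coagulation-network model. The same machinery is
re-implemented so the sub-models can be recalibrated from any
time-course table:

* `fit_q()` — one-parameter regression through the origin of reference
  sensitivity indices on INR/VII ratios;
* `fit_logistic_family()` — joint nonlinear least squares for
  $(a_0, a_1, b_0, b_1)$ across dose levels, $p$ fixed at 0.300 by
  default (estimates for $p$ in the source system ranged 0.26–0.30 and
  fixing it changed the fit negligibly) or free;
* `fit_quadratic_family()` — joint least squares for
  $(c_0, c_1, s_0, s_1)$ under the no-intercept quadratic;
* `derive_slope_series()` — sensitivity-index slope from a time course
  by central differences (second-order one-sided stencils at the grid
  ends, so boundary truncation error is $O(\Delta t^2)$ like the
  interior).

Fitting uses Levenberg–Marquardt (`minpack.lm::nlsLM`) with five
deterministic multi-start perturbations; %RSE comes from the linearised
(Jacobian-based) covariance, the standard approximation in nonlinear
regression (the original report does not state its method). The
per-dose-then-joint two-stage procedure used originally is collapsed
into a single joint fit; a per-dose variant
(`fit_logistic_per_dose()`) is kept for diagnostics.

The objective is unweighted least squares by default, matching the most
plausible reading of the original fits. For data with proportional
(constant-CV) error, `weighting = "proportional"` applies $1/y^2$
weights — the correct objective under that error model, and the one
under which the reported standard errors have their nominal coverage.
Our seeded simulations (100 replicates, 5% proportional noise) show
3-standard-error coverage of at least 93% for every constant under
proportional weighting.

## What the synthetic generator does and does not emulate

`synthetic_patient()` + `simulate_time_course()` construct data that are
*exactly* consistent with the empirical system: the sensitivity index
evolves by the logistic slope at the true reference dose, factor VII
declines mono-exponentially (6 h half-life) to a plateau, and the INR is
back-solved from the proportional approximation, so noiseless output
satisfies $INR \cdot q / VII = SI$ identically. Optional measurement
noise is proportional log-normal with unit mean, applied independently
to INR and factor VII after the deterministic construction, under an
explicit seed.

The factor VII plateau follows an invented saturating dose-response,
$f_{ss}(D) = 1 - 0.5\,D/(D + 6)$ (half-maximal dose 6 mg/day, at most
50% suppression). Two considerations fixed these values: the suppression
must be mild enough at 1 mg/day that the constructed INR is
non-decreasing up to steady state (the rate at which factor VII falls
must not outpace the accrual of the sensitivity index near $t=0$), and
the plateau should be reached within the first two days, consistent with
the 6 h half-life. Real steady-state factor VII suppression at
therapeutic doses is typically deeper than this surrogate's; the choice
affects only the realism of simulated INR magnitudes, not the
correctness of any algorithmic path, because the predictor consumes INR
and factor VII only through the constructed identity. Likewise the
generator makes no attempt to reproduce the mechanistic
coagulation-network trajectories that originally produced the training
data — so passing round-trip tests demonstrate internal consistency of
the implementation, not clinical accuracy on real patients.

Problem sizes used in the test suite and the reproduction script were
chosen for precision at interactive speed: time-course grids of 0.1–0.5
days over 30 days, 100 randomized integral instances, 100 seeded
calibration replicates, and 500 noisy-recovery replicates.

## Known limitations

* Two real-world behaviours are out of scope by design: variable dosing
  (the model applies from the most recent dose-rate change only) and
  covariate-based individualisation (genotype, interactions).
* The supported envelope is doses 1–13 mg/day and INR 1.4–4.7;
  predictions outside it are flagged as extrapolation.
* At very low reference doses the logistic family under-predicts the
  time to steady state relative to the mechanistic model it summarises
  (the 1 mg/day typical-patient case); the steady-state INR itself
  remains accurate there.
* Measurement noise propagates steeply: the observed slope is a small
  difference of two noisy indices, so single-pair estimates of
  $D_{ref}$ at 10% assay CV are individually imprecise even though the
  median across replicates is unbiased. Averaging repeated pairs, or a
  third sample, would tighten this; neither is modelled here.
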
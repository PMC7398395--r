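---
title: "Modelling antiretroviral concentrations in hair as a fraction of the plasma trough"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling antiretroviral concentrations in hair as a fraction of the plasma trough}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpk)
```

## The problem

Hair accumulates systemically circulating drug over weeks, so the drug
concentration in a hair sample integrates exposure — and therefore
adherence — over a much longer horizon than a single plasma sample. In
adolescents on ritonavir-boosted atazanavir (ATV/r 300/100 mg once
daily), hair concentrations of both drugs can be measured by LC-MS/MS,
but interpreting them requires a pharmacokinetic link between what is in
plasma and what ends up in hair. `hairpk` implements a joint plasma–hair
population model for exactly this design: hair sampled at two occasions
(enrolment and a day-90 follow-up), no plasma concentrations available,
and plasma disposition fixed to literature values.

## Structural model

Drug mass moves through a depot ($A_1$), a central compartment ($A_2$)
and a hair compartment ($A_3$):

$$
\frac{dA_1}{dt} = -k_{12} A_1, \qquad
\frac{dA_2}{dt} = k_{12} A_1 - k_{20} A_2, \qquad
\frac{dA_3}{dt} = F_{rac}\, k_{20}\, A_2,
$$

with $k_{20} = CL/V_c$ and the hair concentration read out as
$C = A_3 / V_h$ with $V_h$ fixed to 1. Plasma parameters are fixed:
$k_{12} = 0.44\,h^{-1}$, $CL/F = 10$ L/h, $V_c = 63.4$ L for atazanavir
and $2.31\,h^{-1}$, $12.8$ L/h, $105$ L for ritonavir, with allometric
body-weight scaling ($W^{0.75}$ on clearance, $W^1$ on volume, reference
70 kg). The single-dose solution is the Bateman function; repeated
once-daily dosing is handled analytically by superposition, giving the
steady-state trough

$$
C_{trough} = \frac{D}{V_c}\frac{k_{12}}{k_{12}-k_{20}}
\left[\frac{e^{-k_{20}\tau}}{1-e^{-k_{20}\tau}} -
      \frac{e^{-k_{12}\tau}}{1-e^{-k_{12}\tau}}\right],
\qquad \tau = 24\,h .
$$

`integrate_system()` provides the ODE route (deSolve, relative tolerance
$10^{-8}$, absolute $10^{-10}$, doses as bolus events); the test suite
holds the two routes to $10^{-6}$ relative agreement and enforces the
mass balance $A_3 = F_{rac}(D_{tot} - A_1 - A_2)$. When
$|k_{12}-k_{20}| < 10^{-8}$ the degenerate limit
$(D/V_c)\,k\,t\,e^{-kt}$ is used.

## The hair observation model

The observed quantity is a hair concentration (ng drug per mg hair); the
model predicts it as a *fraction of the steady-state plasma trough*:

$$
y_{ij} = f_{ij}\,(1+\varepsilon_{prop}) + \varepsilon_{add},
\qquad
f_{ij} = F_{rac,ij}\; T_i / V_h ,
$$

where $F_{rac,ij}$ is the covariate-adjusted fraction for subject $i$ at
occasion $j$ and $T_i$ is the subject's steady-state trough. Two
conventions had to be fixed here, and both are package design choices
documented as such:

**Units.** Plasma troughs (mg/L) and hair concentrations (ng/mg) are not
dimensionally reconcilable with $V_h = 1$, so the model works in an
internal concentration unit: the mg/L trough times `trough_scale = 100`
(i.e. µg/dL). With the atazanavir typical trough of 0.171 mg/L this puts
$F_{rac} = 0.16$ predictions at $\approx 2.7$ ng/mg — the magnitude hair
assays actually report — and makes the additive error SD (0.30 in hair
units) and the assay limits (0.05 / 0.01 ng/mg) meaningful on the same
scale. Any remaining absolute scale is absorbed into $F_{rac}$, so the
fraction is estimable regardless of the unit choice.

**Which trough.** By default (`link = "population"`) $T_i$ is the
*typical* trough from the weight-scaled plasma parameters, so the
fraction is a ratio against the typical trough and plasma
inter-individual variability (IIV) does not propagate into the hair
prediction. The alternative (`link = "individual"`) computes $T_i$ from
eta-perturbed individual parameters. The population link is the default
for a quantitative reason: at $k_{20}\tau \approx 3.8$ the steady-state
trough is exponentially sensitive to clearance
($\partial \log T / \partial \log CL \approx -3.3$), so a clearance IIV
variance of the magnitude reported for this drug class (around 1 on the
log scale) would imply hair concentrations dispersed over five or more
orders of magnitude — far beyond the roughly two-log range hair assays
observe — and would swamp any between-subject covariate signal. At
steady state the amount a dosing interval deposits in hair is
$F_{rac} D$ irrespective of $CL$, $V_c$, $k_{12}$, which is also why a
clearance-variance estimate in this design carries enormous uncertainty:
the hair data are nearly uninformative about plasma IIV. Under the
population link those variances are therefore carried as fixed
descriptors and not estimated; under the individual link they are
estimable and the whole Laplace machinery applies to them (exercised in
the test suite at small scale).

## Covariate model on the fraction

$$
F_{rac,ij} = F_{rac}^{pop}
(1+\beta_{occ}\,\mathbb{1}[\text{enrolment}])\;
e^{\beta_{adh}(VAS_{ij}-84.2)}\;
(1+\beta_{bmi[i]})\;
(1+\beta_{cg[i]}),
$$

with reference levels follow-up occasion, normal BMI-for-age and
grandparent caregiver. Categorical effects are proportional-linear, so a
coefficient of $-0.30$ reads directly as "30% lower". The continuous
adherence score uses the exponential form for a structural reason: with
the score centred at the cohort mean (84.2) and the plausible score
range extending to 30, a linear factor $1+\beta(VAS-84.2)$ turns
negative below a score of ~34 for $\beta = 0.02$ — i.e. a 2%-per-unit
effect of the size actually observed cannot be represented linearly over
the observable score range. $e^{\beta x}$ is always positive and reads
as the same 2% per unit locally. Evaluation validates every factor and
names the offending covariate if one is driven non-positive.

Random effects are log-normal with diagonal covariance; the variance of
an optional inter-occasion effect on the fraction
(`omega2_frac_iov`) defaults to 0 (off). Residual error combines
additive and proportional components,
$sd(f) = \sqrt{(sd_{prop} f)^2 + sd_{add}^2}$.

## Quantification limits

Assay ranges are 0.05–20.0 ng/mg (ATV) and 0.01–4.0 ng/mg (RTV). Only
quantifiable records enter the likelihood. By default
(`blq_method = "M2"`) each retained record's density is conditioned on
being quantifiable — divided by $P(y \ge LLOQ)$ — which keeps the
estimator consistent under left-truncation; plain exclusion
(`blq_method = "M1"`) is available but demonstrably attenuates effects
whose groups are censored asymmetrically (an enrolment effect of $-0.42$
recovers at $\approx -0.36$ under plain exclusion at a ~5% censored
fraction). A full censored-data likelihood (treating BLQ records as
interval observations) is a documented extension point, not implemented.
Values at exactly the limit count as quantifiable (closed lower bound).
Above-range values are counted but not censored.

## Estimation

`fit_hair_model()` minimises a Laplace approximation of
$-2\log$ marginal likelihood: per subject, the conditional mode
$\hat\eta_i$ of $\log p(y_i|\eta) + \log p(\eta)$ is found by BFGS
(started at $\eta = 0$ every outer iteration, for determinism), and

$$
OFV = \sum_i -2\left[\ell_i(\hat\eta_i) + \tfrac{d}{2}\log 2\pi -
\tfrac12 \log\det H_i\right],
$$

with $H_i$ the negative Hessian of the inner objective (finite
differences, symmetrised, eigenvalue-floored with a warning if not
positive definite). The residual SD depends on $\eta$ through the
prediction, so the interaction term is respected. This is the full
Laplace member of the conditional-estimation family rather than a
re-implementation of the classical first-order linearisation: it has a
cleaner contract and can be tested against quadrature. With no active
random effects the OFV is the exact Gaussian deviance.

The outer problem runs `nlminb` on transformed parameters (log scale for
the fraction, variances and error SDs; box constraints keeping every
covariate factor positive), restarts from its own optimum until the
objective is stable (so nested-model comparisons are reliable at the
0.01 level), and reports standard errors from the inverse of the
numerically differentiated outer Hessian (delta method back to the
natural scale; plain SEs, no sandwich). An optimiser "false/singular
convergence" code at an optimum that restarts confirm stable is treated
as converged — this is routine when a candidate coefficient starts at
exactly zero.

`quadrature_ofv()` is the in-package oracle: adaptive Gauss–Hermite
quadrature centred and scaled at the conditional modes (tensor grid, at
most two dimensions, log-sum-exp accumulation). The acceptance suite
holds Laplace within 0.5 OFV units of the 32-node oracle across a
randomised set of small nonlinear instances and to $10^{-6}$ of the
analytic marginal for linear-in-eta models, where Laplace is exact.

## Covariate selection, bootstrap, diagnostics

`run_scm()` does forward inclusion then backward elimination on the
fraction only. Thresholds default to $\chi^2$ quantiles matched to each
relation's degrees of freedom (0.05 forward: 3.84 / 5.99 / 7.81 for
1 / 2 / 3 df; 0.01 backward: 6.63 / 9.21 / 11.34); a fixed-constant mode
(3.83 / 6.64 for every candidate) reproduces the conventional 1-df
quoting. One best candidate is accepted per forward round (largest
ΔOFV; ties to fewer df, then name); candidates whose fits fail are
skipped, not fatal. The audit trail records every evaluation with its
ΔOFV, threshold, decision and cumulative df.

`run_bootstrap()` resamples subjects with replacement (all occasions of
a drawn subject travel together, re-identified uniquely), refits each
resample starting from the original estimates, and summarises converged
resamples with medians and 90% percentile intervals (type-7 quantiles;
the percentile method is used because no interval method was mandated).
More than 50% refit failure flags the result unreliable. Resampling is
unstratified by default, with an option to stratify by occasion count.

Diagnostics compute population predictions ($\eta = 0$), individual
predictions (at $\hat\eta$), IWRES
$(y - f(\hat\eta)) / sd(f(\hat\eta))$, and CWRES from the standard
first-order expansion about the conditional modes:
$V^{-1/2}(y - f(\hat\eta) + G\hat\eta)$ with $G = \partial f /
\partial\eta$ (central differences, relative step $10^{-5}$) and
$V = G \Omega G^\top + \mathrm{diag}(sd^2)$, the inverse square root by
symmetric eigendecomposition. With no random effects CWRES reduces
exactly to the weighted residual. On data simulated at the truth the
suite requires |mean CWRES| ≤ 0.05 and SD within 0.05 of 1 at $10^4$
records.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design so the whole pipeline runs
without any external data: n = 50 adolescents by default, two occasions
(days 0 and 90), both analytes, BMI-for-age at 54/30/15% (the published
percentages renormalised — they sum to 99), caregiver at 40/20/30/10%,
adherence VAS normal (mean 84.2, SD 18.1) truncated to [30, 100] and
shared across occasions (a per-occasion option exists), and body weight
log-normal (median 50 kg, CV 20%, bounds 25–90 kg) — weight is not
reported by the study, and the choice is immaterial to fraction recovery
because the same weights enter simulation and refitting. Inverse-CDF
sampling keeps truncated draws exact and reproducible; the caller's RNG
state is preserved. Note the realised VAS mean is 78.2, not 84.2: both
tails are truncated asymmetrically.

What the generator does *not* emulate — and hence what green tests do
not certify about real hair data: the study's higher BLQ fractions
(18%/12%; severely non-adherent subjects with near-zero exposure are not
produced by a 2%-per-unit adherence effect, so simulated BLQ rates are a
few percent), hair growth-rate variation and position-along-shaft
kinetics, cosmetic hair treatment, drug–drug interactions, and any
misspecification of the plasma constants. Parameter recovery on this
generator demonstrates estimator correctness under the model, not model
correctness for real cohorts.

A known small-sample behaviour worth flagging: in a covariate-free
design the predictions are nearly constant across records, so the
additive/proportional error split sits on a likelihood ridge; at n = 50
the additive component can run to ~0 with an enormous SE. The
full covariate models are identified (the covariates spread the
predictions), and the calibration experiments estimate an identifiable
subset instead.

## Problem sizes used by the automated checks

Parameter recovery refits cohorts of 500 subjects × 2 occasions, five
replicate seeds per analyte, and compares medians (tolerances: 1
percentage point on the fraction, 0.03 absolute on covariate
coefficients). Selection calibration uses 200 null datasets and 20
effect datasets at n = 100; bootstrap coverage uses 50 replicates × 200
resamples at n = 100; residual calibration uses $10^4$ records. These
sizes make the full suite run in a few minutes while keeping Monte-Carlo
error well inside the asserted bands.
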
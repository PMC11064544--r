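---
title: "Population pharmacokinetics of once-daily dolutegravir/lamivudine: models, simulation and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of once-daily dolutegravir/lamivudine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlpoppk)
```

## Scope

`dlpoppk` implements a complete, testable population-pharmacokinetic
workflow for the once-daily dolutegravir 50 mg / lamivudine 300 mg
fixed-dose combination at steady state in virologically suppressed adults:
the two final nonlinear mixed-effects models, a virtual-population
generator that emulates the originating study design, approximate
maximum-likelihood estimation with covariate selection and bootstrap,
noncompartmental steady-state exposure metrics with a covariate
forest-plot trial simulation, and the standard simulation-based model
diagnostics (pcVPC, NPDE, goodness-of-fit). Individual-level study data are
not publicly deposited, so every downstream stage is exercised against
simulated data generated by the package itself; what that does and does
not demonstrate is discussed at the end.

## The structural and statistical models

Dolutegravir follows a one-compartment model with first-order absorption
and elimination; lamivudine a two-compartment model with first-order
absorption, with the peripheral volume constrained equal to the central
volume (V3/F = V2/F), a constraint adopted because freely estimated
peripheral volumes are not reliably identifiable from predominantly sparse
sampling. All parameters are apparent (oral) values with bioavailability
fixed at 1.

Individual parameters are built multiplicatively. For dolutegravir,

CL/F_i = 0.858 x (WT/79)^0.427 x (BILI/8)^-0.153 x 0.844^ETHN x exp(eta_CL),
V/F_i = 16.7 x (WT/79)^0.917, Ka_i = 2.15 h^-1,

with ETHN an indicator for Hispanic/Latino ethnicity. For lamivudine,

CL/F_i = 19.6 x (WT/70)^0.75 x (eGFR/99)^0.533 x 0.789^RACE x exp(eta_CL),
V2/F_i = V3/F_i = 105 x (WT/70) x exp(eta_V2), Q/F_i = 2.97 x (WT/70)^0.75,
Ka_i = 2.30 h^-1,

where RACE indicates Black/African American and the weight exponents are
fixed allometrically (0.75 on clearances, 1.0 on the volume) rather than
estimated. Random effects are log-normal; for lamivudine (eta_CL, eta_V2)
are jointly normal with covariance -0.0531 (correlation about -0.45).

The residual model is proportional with a subject-level magnitude:

Y = IPRED x (1 + theta_prop x exp(eta_RUV) x epsilon), epsilon ~ N(0, 1),

with theta_prop 0.341 (dolutegravir) and 0.359 (lamivudine) and a variance
on eta_RUV of 0.0567 and 0.247 respectively. Giving the error magnitude
its own inter-individual term absorbs subject-to-subject differences in
effective data quality (e.g. imperfect dosing histories). The reported
variance-to-%CV transform is the exact log-normal relation
`100 * sqrt(exp(omega^2) - 1)` (`iiv_percent_cv()`).

Units are deliberately uniform: doses in mg, volumes in L, clearances in
L/h, times in h, so predicted concentrations are mg/L, numerically equal
to ug/mL. Assay quantification limits (20 ng/mL dolutegravir, 2.5 ng/mL
lamivudine) are carried as 0.020 and 0.0025 ug/mL.

## Steady-state closed forms

Concentrations are predicted by closed-form superposition at steady state:
every exponential `exp(-lambda t)` of the single-dose oral solution
acquires the accumulation factor `1/(1 - exp(-lambda tau))`. For the
two-compartment model the hybrid disposition roots alpha and beta come
from the micro-constants (k10 = CL/V2, k12 = Q/V2, k21 = Q/V3) via
alpha + beta = k10 + k12 + k21 and alpha x beta = k10 x k21. Two numerical
choices matter:

* **Near-coincident rate constants.** When |ka - k|/k < 1e-8 (or a hybrid
  root collides with ka, or alpha with beta), the implementation switches
  to the analytic confluent limit, which replaces the 0/0 ratio with the
  derivative term `t exp(-kt)` plus its accumulation correction. This
  avoids the catastrophic cancellation a perturbation approach would
  merely mask. Continuity across the switch is tested.
* **Closed form over ODE integration.** Multi-dose ODE integration to
  periodicity is kept as a test oracle only (agreement within 1e-6
  relative after 40 dosing intervals); the closed form is exact and orders
  of magnitude faster, which the trial simulations rely on.

Both forms satisfy the steady-state identities used as invariants:
C(0) = C(tau) and the integral of C over one interval equals dose/CL.

## The virtual population

`population_spec()` encodes the analysis population: 361 subjects, 30 of
whom form an intensive-sampling subset. Continuous baseline covariates
(weight, height, bilirubin, eGFR, age, creatinine clearance, albumin) are
drawn from truncated log-normal distributions anchored at the study median
with the printed range treated as the expected extremes of a sample of a
few hundred (about +/-2.7 SD on the log scale); draws are truncated to the
printed range, so the support can never exceed what was observed.
Categorical covariates are Bernoulli at the printed proportions (19.3%
Hispanic/Latino, 13.5% Black/African American, 93.1% male, smoking
categories as observed). Body surface area is computed from weight and
height (DuBois) rather than drawn, keeping the size variables mutually
consistent. One further dependence is imposed because it is structural,
not incidental: the study computed eGFR with the 2009 CKD-EPI equation,
whose race coefficient multiplies eGFR by 1.159 for Black/African American
subjects. The generator scales a common base draw accordingly (capped at
the observed maximum, base median rescaled so the overall median stays at
99). This matters downstream: the race effect on lamivudine clearance
(multiplier 0.789) is partly offset by the systematically higher eGFR of
the same subgroup, and without the coupling the Black-category exposure
ratio would sit right on the 1.25 edge of the bioequivalence band instead
of comfortably inside it, as the originating analysis found. No other
covariate correlations are imposed: the joint distribution of the real
cohort is unavailable, and this remains the main respect in which the
generator is weaker than the original data -- other category contrasts
that were partially confounded in the study (and flagged as such there)
are clean here by construction.

Sampling follows the study schedule: the intensive subset contributes a
ten-point week-4 profile (pre-dose, 0.5, 1, 1.5, 2, 3, 4, 6, 10, 24 h);
every subject contributes sparse samples -- week 4 pre-dose and 1 h, one
sample in each of the 1-4 h and 4-12 h windows at weeks 8/12 (window order
alternating between subjects), and pre-dose at weeks 24, 36 and 48.
Realised sparse times are uniform within their windows, the simplest
defensible choice given that realised times are not published. Simulated
concentrations below the quantification limit are flagged and excluded
from estimation rather than modelled, mirroring the originating analysis
(which had only ~0.1-0.2% such samples and did not attempt
below-quantification likelihood methods). A contamination mechanism for
aberrant pre-dose samples (reported at ~2% in the real data) is *not*
simulated: no contamination model is published, and adding an arbitrary
one would only blur what the diagnostics are being validated against.

## Estimation

`ofv()` returns -2 times an approximate marginal log-likelihood. Per
subject, the random-effect vector is optimised to its posterior mode
(empirical Bayes estimate) by a damped Newton method whose curvature is
the Fisher/Gauss-Newton information of the heteroscedastic Gaussian
observation model -- the interaction of the random effects with the
residual variance (through both the prediction and `eta_RUV`) is kept
throughout. The Laplace normalising term uses an exact central
finite-difference Hessian of the penalised deviance at the mode (step
1e-3), falling back to the always-positive-definite Gauss-Newton
information if that Hessian is not positive definite. The exact Hessian
matters: with the Gauss-Newton curvature alone, null likelihood-ratio
statistics for spurious covariates were visibly inflated in calibration
runs; with it, the null distribution on an information-rich design matches
chi-square(1) closely (Q-Q slope within a few percent of 1, false
retention at the 6.63-point forward threshold equal to the nominal 1% in
200-simulation runs at 40 subjects x 8 samples). On very sparse designs a
residual inflation remains, consistent with what is well documented for
linearisation-based estimators; the calibration test therefore uses the
rich design on purpose, and covariate decisions on sparse real designs
should lean on the stricter backward threshold.

The outer problem maximises the approximate likelihood over structural
parameters (log scale), estimated covariate coefficients (identity for
exponents, log for categorical ratios), the residual magnitude (log) and
the random-effect block (log variances, atanh correlation), using a
quasi-Newton minimiser. Per-subject modes are warm-started from anchors
that are frozen during each optimiser run and refreshed between runs,
keeping the objective an exactly deterministic function of the parameters
-- letting warm starts drift *within* a run injects enough noise into
finite-difference gradients to trigger spurious "false convergence"
stops. Convergence is declared when the optimiser reports success or when
a restarted run reproduces the objective within 1e-3 points without
moving. Multi-start (jittered initial values, `control$n_starts`) is
available for cold-start problems but defaults to a single start: in this
workflow initial values come from the known generating model, a previous
step of the search, or the original-fit estimates (bootstrap), where
additional starts add cost without benefit. Standard errors, when
requested, come from a finite-difference Hessian of the objective at the
optimum, reported as %RSE.

Covariate selection follows the forward/backward objective-value
procedure: greedy forward addition accepting the best candidate per round
if the objective drops by at least 6.63 points (chi-square(1) at alpha
0.01), then backward elimination removing any searched term whose deletion
costs less than 10.83 points (alpha 0.001). Candidates start neutral
(exponent 0, ratio 1). `refit = "coef"` offers a fast screen that profiles
only the candidate coefficient at frozen base estimates; the default
refits everything. The nonparametric bootstrap resamples subjects with
replacement, refits every replicate, reports medians and 2.5/97.5
percentiles over converged replicates, and reports the converged fraction
rather than hiding failures.

## Exposure metrics and the forest simulation

Steady-state profiles are predicted on the nine-point grid 0, 1, 2, 3, 4,
6, 8, 12, 24 h. AUC0-tau uses the linear-up/log-down trapezoid (log
segment only when both endpoints are positive and falling), Cmax is the
grid maximum and Ctau the 24-h value. Taking Cmax from the grid slightly
underestimates the continuous maximum (the typical dolutegravir peak falls
between grid points at about 1.6-1.8 h); this matches how the grid is
specified upstream and is accepted as-is. The grid AUC sits within 2.5% of
the analytic dose/CL for both drugs' typical subjects, which bounds the
discretisation error carried into population summaries.

Exposure summaries are geometric means with log-scale t-intervals, split
by covariate category or by sample quartiles (boundary ties to the lower
bin; the upstream quantile convention is unstated, and at n = 361 the
choice is immaterial). Two posterior modes are supported deliberately:
post hoc summaries from empirical Bayes estimates of a fit (the analysis
path), and fresh random-effect draws per trial (the simulation path used
by the forest plot).

`forest_simulation()` repeats the virtual study (default 1,000 trials;
the packaged checks use 200 to keep runtimes short): each trial redraws
every subject's random effects, computes per-subject metrics, and takes
geometric means per category/quartile. Each trial's category means are
normalised by the median across trials of the overall-population geometric
mean, and the summary reports the median and 2.5th/97.5th percentiles of
the normalised ratios, judged against the 0.8-1.25 bioequivalence band.
With the final models and the calibrated population, all AUC category
medians fall inside the band; the largest excursions (about 1.15-1.19)
come from the extreme lamivudine eGFR and race categories, whose 0.533
exponent and 0.789 multiplier are the strongest clearance effects in
either model.

## Diagnostics

The pcVPC follows the prediction-correction construction: each observation
(and each simulated replicate) is scaled by the ratio of its time-bin's
median typical-value (eta = 0) prediction to its own typical-value
prediction; bins are quantile-based on time after dose (default 8, merged
below 10 observations -- binning is unstated upstream and quantile bins
keep counts balanced across the intensive/sparse mix). Percentiles 5/50/95
of the corrected observations are compared with simulation-based
confidence bands. NPDE uses the standard decorrelation construction
(centre on the simulation mean, decorrelate with the Cholesky factor of
the simulation covariance, rank among decorrelated simulations, map to
normal quantiles, with a flagged ridge fallback for singular covariances).
Null calibration (data simulated from the evaluated model) and negative
controls (halved clearance for the pcVPC, doubled residual magnitude for
the NPDE) are part of the test suite. Goodness-of-fit tables report
typical and individual predictions, individually weighted residuals, and
conditional weighted residuals from the first-order expansion around the
posterior modes.

## Problem sizes used by the packaged checks

The packaged test suite and acceptance script run everything at sizes
chosen to keep the whole suite comfortably reproducible on a laptop while
leaving Monte-Carlo slack well below the tolerances being asserted:
exposure geometric means at the full n = 361 with one random-effect draw
per subject (Monte-Carlo SE about 1.4% against a 5% band), the forest at
200 trials, parameter-recovery fits at 120-200 subjects with the 30-subject
intensive subset, the null likelihood-ratio calibration at 200 simulated
studies of 40 rich-sampled subjects, and diagnostics at 50-100 subjects
with 120-500 replicate simulations. These are the package's own choices of
scale; the functions accept the full-size settings directly.

## Known limitations

* Covariate correlations (beyond the size variables) are not reproduced,
  so quartile-contrast percentages that depend on the real joint
  distribution are out of reach by design.
* The reported dolutegravir Cmax geometric mean (5.08 ug/mL) is well above
  what the reported fixed effects imply for a typical subject on the
  nine-point grid (about 3.9); the upstream analysis itself notes its Cmax
  ran high against historical data. Cmax is therefore summarised but not
  held to a quantitative check anywhere in the package.
* The estimator is a Laplace-type approximation: its null calibration is
  demonstrated on information-rich designs and degrades on very sparse
  ones, as linearisation-based methods are known to do.
* Between-occasion variability, absorption lag/transit models and
  below-quantification likelihood methods are deliberately out of scope;
  the first two were not supported by the originating data, the last was
  unnecessary at ~0.1-0.2% affected samples.
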
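---
title: "Population pharmacokinetics of ophthalmic atropine in horses: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of ophthalmic atropine in horses: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atropk)
```

## The problem

Topical ophthalmic atropine is a mainstay of equine uveitis treatment, but
systemically absorbed atropine suppresses gut motility and frequent dosing
has been associated with colic. The question this package addresses is
quantitative: how much atropine reaches plasma after an eye drop or a
constant-rate ocular infusion, how fast is it cleared, and which dosing
regimens keep plasma exposure in a range where gastrointestinal side effects
are unlikely?

The package implements a complete population-pharmacokinetic workflow for
this setting: a two-compartment disposition model with three input routes,
Laplace-approximate maximum-likelihood estimation with censored
below-quantification data, bootstrap precision intervals, standard
goodness-of-fit diagnostics (CWRES, VPC), and deterministic plus Monte Carlo
regimen simulation. A synthetic-study generator reproduces the design of the
underlying six-horse crossover experiment so that every stage can be
validated end to end without animal data.

## Structural model

Atropine disposition is described by a linear two-compartment model
parametrised in clearances and volumes, all per kg body weight:

* `Vc`, `Vt` — central and peripheral volumes (L/kg),
* `Cl` — plasma clearance (L/kg/h),
* `Cld` — inter-compartmental distribution clearance (L/kg/h),
* `ka` — first-order rate constant (1/h) for transfer from the ocular
  deposit to plasma,
* `F_drop`, `F_inf` — bioavailabilities of the eye-drop and infusion routes,
  estimated on the logit scale so they cannot exceed 1.

Three inputs are supported: an intravenous bolus into the central
compartment, an eye-drop bolus into the ocular depot (first-order transfer
of `F_drop · dose`; no lag time), and a zero-order ocular infusion scaled by
`F_inf`. Because the system is linear, arbitrary regimens are evaluated by
superposition of closed-form single-dose solutions — a biexponential for the
IV bolus, a triexponential for the depot route, and the standard ramp/decay
form for the infusion. The closed forms, not a numerical integrator, are
used everywhere (exactness and speed matter in the estimation inner loop);
an independent `deSolve` integration serves as the oracle in the test suite.

With hybrid rate constants `k10 = Cl/Vc`, `k12 = Cld/Vc`, `k21 = Cld/Vt`,
the disposition exponents are the roots of
`s^2 - (k10 + k12 + k21) s + k10 k21`: `alpha` (fast) and `beta`
(terminal). Secondary parameters follow: half-lives `ln 2 / rate`,
`Vss = Vc + Vt`, `MRT = Vss / Cl`, and `F = exp(logit)/(1 + exp(logit))`.

A numerical subtlety is specific to this drug: absorption is almost as fast
as distribution (absorption half-life 0.117 h vs alpha half-life 0.077 h at
the typical values), so `ka` can collide with a disposition exponent and the
standard triexponential coefficients become ill-conditioned. The depot
solution is therefore evaluated as a divided difference of
`f(lambda) = (k21 - lambda) e^{-lambda t}` over `{ka, alpha, beta}`, which
switches to the confluent (repeated-root, `t e^{-lambda t}`) form whenever
two rates agree to within a relative 1e-8. The profile is continuous through
the collision; a test sweeps `ka` through `alpha` to confirm it.

## Statistical model

Inter-individual variability follows the exponential model
`param_i = tv · exp(eta_i)`, `eta_i ~ N(0, omega²)`, with a diagonal omega
over `Vc`, `Cl`, `Vt`, `Cld` and the two logit-scale bioavailabilities; `ka`
carries no random effect (the sparse absorption-phase sampling cannot
support one). Applying the multiplicative model to the *logit-scale*
bioavailability typicals keeps every individual's `F` in (0, 1) and matches
how the variability of these parameters is reported; it requires positive
logit-scale typical values, which holds comfortably here (0.781, 0.738).
One eta vector is shared by all three of a subject's occasions: the
published final model carries no inter-occasion variability, and the
crossover's three-week washouts make occasions kinetically independent. An
optional inter-occasion deviation on `Cl` (`iov_cl`) is available in the
simulation-side generator for sensitivity exercises, but the estimation path
deliberately refuses it — it is not part of the validated model.

Residual error is additive plus proportional,
`C_obs = C(t) · (1 + eps1) + eps2`, so the observation SD at prediction `c`
is `sqrt(sigma_prop² c² + sigma_add²)`. Samples below the assay's lower
limit of quantification (LOQ, 0.05 µg/L) are *censored, not discarded*: a
BQL record contributes the normal probability mass below the LOQ,
`Phi((LOQ - c)/sd)`, the M3 likelihood. This matters here because roughly
half of a six-horse study's samples are BQL.

### Estimation

The marginal likelihood integrates the per-subject etas out of the joint
density. The package uses the Laplace approximation: for each subject the
penalised objective `g(eta) = -log p(y|eta) + ½ eta' Omega^{-1} eta + const`
is minimised by a damped Newton search (finite-difference gradient and
Hessian, tolerance 1e-9 on the gradient norm, restart from the prior mean on
failure), and the subject's contribution is
`2 g(eta_hat) - d log(2*pi) + log det H`. The approximation is exact when all
omegas are zero, and on one-subject problems it agrees with 64-node
Gauss-Hermite quadrature to well under 0.5% (both are test assertions).

The outer search maximises the marginal likelihood over the seven typical
values, the active omega diagonal and the two residual SDs, all
log-transformed to enforce positivity, with `nlminb`. Two numerical choices
are worth recording:

* **Explicit gradient.** The objective is smooth but carries ~1e-9
  reproducibility noise from the numerically located inner modes.
  `nlminb`'s internal machine-epsilon-scale difference quotients drown in
  that noise and the search stalls with spurious "false convergence"
  reports; a central difference with step 1e-5 on the log scale restores
  accurate gradients. Inner searches are warm-started from the previous
  outer iterate, which keeps one full objective evaluation near 5 ms for a
  six-horse study.
* **Convergence certification.** On this likelihood surface (6 horses, 15
  parameters, several weakly identified variance components) the optimizer
  can terminate on a flat ridge. A fit is accepted as converged when a
  search restarted at the solution improves -2LL by less than 0.01 — on the
  deviance scale, changes that small are statistically immaterial. Fits that
  keep improving are flagged `converged = FALSE` but still return their
  estimates.

Post-hoc (empirical Bayes) etas are the inner modes at the final estimates.
From them the fit reports `PRED` (etas = 0), `IPRED`, shrinkage
`1 - var(eta)/omega²` (flagged above 0.3, where the IIV% loses
credibility), IIV CV% `100·sqrt(exp(omega²)-1)`, and
`AIC = -2LL + 2·(n_theta + n_omega + n_sigma)`.

## Diagnostics

**CWRES.** Conditional weighted residuals linearise the model about the
post-hoc etas: with `G = df/deta` at the mode, the approximate moments are
`E[y] = f(eta_hat) - G eta_hat` and `Cov = G Omega G' + diag(residual
variance at f(eta_hat))`, and the residuals are whitened by the Cholesky
factor of `Cov`. Under the true model they are approximately standard
normal; the suite checks mean within ±0.1 and SD within [0.9, 1.1] on a
self-simulated 60-horse study. BQL points carry no residual.

**VPC.** The visual predictive check simulates replicate studies under the
fitted model with the original design and compares observed 20th/50th/80th
percentiles per time bin and route with the medians of the simulated
percentiles. Censoring is treated symmetrically: simulated values below the
LOQ are set to LOQ/2 for ranking, exactly as observed BQL records are. Bin
centers default to the scheduled sampling times of each route (the natural
choice for a protocol with nominal times); each observation joins its
nearest center, and an empty bin is an error rather than a silent gap.

## Bootstrap

Parameter precision is estimated by a nonparametric bootstrap that resamples
*subjects* with replacement — a horse's three occasions travel together,
preserving the crossover structure — and refits each replicate starting from
the original point estimate. Secondary parameters are computed per replicate
and then summarised (median, CV%, 2.5/97.5 percentiles). The order of those
two steps is deliberate and visible in the reported tables: medians commute
with monotone transforms (the median absorption half-life is exactly
`ln 2 /` the median `ka`) but not with sums or ratios, so the median
steady-state volume is *not* the sum of the median `Vc` and `Vt`. The
reported default is 1000 replicates; the test suite uses small replicate
counts since it checks machinery, not precision. Non-converged replicates
are dropped and counted, with a warning above 20%.

## Regimen simulation

Two modes reproduce the study's dosing questions:

* `pk_simulate_typical()` solves the model at the typical values (etas = 0,
  no residual noise) for an eye-drop schedule or infusion and summarises
  each dosing interval by peak and trough (the concentration immediately
  before the next dose). The default grid step is 0.005 h (18 s), fine
  enough that the sharp absorption peaks (time-to-peak ≈ 0.4 h) are resolved
  to well under 1%.
* `pk_simulate_population()` draws `n` horses from the inter-individual
  distribution (no residual noise). For a constant-rate infusion each
  horse's steady state is computed exactly as `F_inf,i · rate / Cl_i`,
  avoiding any horizon-truncation bias; the 5th/50th/95th percentiles
  (type-7 quantiles, stated for reproducibility) summarise the population.
  For bolus schedules full profiles are simulated and summarised per time
  point.

At the published parameter values the hourly 1.5 µg/kg eye-drop schedule
accumulates to a steady oscillation of about 0.30–0.83 µg/L
(trough–peak), the three-hourly schedule to troughs near 0.04 µg/L, and the
six-hourly schedule washes out below the LOQ between doses; the 0.5 µg/kg
hourly schedule oscillates between about 0.10 and 0.28 µg/L. A 1000-horse
Monte Carlo of the 5 µg/kg/24 h infusion puts 90% of horses between roughly
0.053 and 0.11 µg/L at steady state. These are the numbers the acceptance
script recomputes; the test suite asserts them at the tolerances under which
they were reported.

## The synthetic-study generator

`pk_study_design()` encodes the study conditions: six horses with body
weights drawn uniformly on 502–642 kg, three occasions each (IV bolus and
eye-drop bolus of 835 µg atropine — 1 mg atropine sulfate, salt factor
0.835, converted to µg/kg with each horse's weight — and a 24-h ocular
infusion at 120 µg/h), bolus sampling at 5–420 min, infusion sampling at
30–1440 min, pre-dose samples, LOQ 0.05 µg/L, and the first infusion sample
flagged excluded (activating the infusion pump can deliver a spurious
initial bolus, so that sample is carried in the file but kept out of the
likelihood). `pk_simulate_study()` then draws etas, evaluates true profiles,
adds combined residual noise, truncates negative simulated concentrations at
zero, and censors values below the LOQ as BQL records. The generating etas
and individual parameters go to a separate truth table so the dataset itself
is schema-identical to a real study export.

What the generator emulates — and what it does not: it reproduces the
design, the stated variability structure, and the censoring mechanism, so
passing recovery tests demonstrate that the estimator is consistent with its
own data-generating assumptions at the study's scale. It does not emulate
assay calibration structure, model misspecification (e.g. a third
compartment, nonlinear elimination), inter-occasion variability unless asked
(`iov_cl`), or correlated random effects; agreement on synthetic data
therefore cannot certify those aspects against real data.

## Problem sizes and runtime choices

The validation experiments are sized to the study they emulate rather than
to asymptotics: the recovery experiment refits 20 replicates of the
six-horse, three-occasion design (the scale at which the published
parameters were estimated), CWRES/VPC calibration uses 60–100 synthetic
horses, the VPC uses 150–400 simulated replicates, Monte Carlo regimen
simulation uses 1000 horses, and in-suite bootstraps use small replicate
counts. At these sizes the whole test suite runs in well under half an hour
on a single CPU.

Known numerical parameters, with defaults: inner Newton gradient tolerance
1e-9 (inner modes must be tight or the outer objective becomes noisy);
outer `nlminb` relative tolerance 1e-9 with at most 500 iterations; restart
certification threshold 0.01 on -2LL; finite-difference steps 1e-4 (inner,
eta scale) and 1e-5 (outer, log-parameter scale); repeated-root switch at
relative 1e-8; regimen grid 0.005 h; steady-state trough flag at relative
1e-3.

## Known limitations

* The estimator is Laplace maximum likelihood: variance components and
  residual SDs carry the usual small-sample ML bias (no REML analogue), and
  with six subjects the omega estimates are volatile, particularly for the
  logit-scale bioavailabilities whose variance is itself large.
* The published secondary-parameter table reports bootstrap medians, which
  are not transforms of the primary medians; pointwise comparisons of
  secondary parameters must go through the bootstrap machinery, not through
  `pk_secondary()` applied to typical values.
* Shrinkage is validated by its formula properties; the published
  per-parameter shrinkage values cannot be reproduced from the published
  rounded post-hoc values and are not asserted.
* CWRES uses the standard first-order conditional linearisation; with
  strongly nonlinear eta effects (the logit bioavailabilities) it is an
  approximation, which is why the calibration test allows mean ±0.1 and SD
  within [0.9, 1.1] rather than exact normality.
* Ocular-tissue concentrations, pharmacodynamic linkage of plasma
  concentration to gut-motility scores, and nonlinear elimination are out of
  scope.
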
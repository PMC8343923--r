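---
title: "Pediatric gentamicin population PK: models, estimation and simulation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pediatric gentamicin population PK: models, estimation and simulation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gentapk)
```

gentapk re-implements, as a tested pipeline, a pediatric gentamicin
population-pharmacokinetic analysis built on sparse therapeutic drug
monitoring (TDM) data: 22 non-critically-ill children (1–72 months,
3.98–17.7 kg) received ~2.26 mg/kg IV gentamicin as 30-minute infusions
every 8 or 12 hours, with exactly one peak sample (half an hour after the
end of the third dose's infusion) and one trough sample (immediately before
the fourth dose) per child. This vignette documents the models, the
estimation machinery, the synthetic-data generator that stands in for the
original dataset, and the numerical choices — including where the design was
genuinely open and what the package decided.

## Structural model

Disposition is linear one- or two-compartment kinetics with zero-order
(infusion) input and first-order elimination. For the two-compartment model
with clearance $CL$ (L/h), central volume $V_c$ (L), peripheral volume $V_p$
(L) and intercompartmental clearance $Q$ (L/h), the micro constants are
$k_{10} = CL/V_c$, $k_{12} = Q/V_c$, $k_{21} = Q/V_p$, and the hybrid rates
$\alpha \ge \beta$ solve $x^2 - (k_{10}+k_{12}+k_{21})x + k_{10}k_{21} = 0$.
A single infusion of rate $R_0$ over duration $T$ contributes, per
exponential term $i$ with unit-impulse coefficient $C_i$,

$$
c(t) = \begin{cases}
R_0 \frac{C_i}{\lambda_i}\left(1 - e^{-\lambda_i t}\right), & t \le T\\[4pt]
R_0 \frac{C_i}{\lambda_i}\left(1 - e^{-\lambda_i T}\right)
  e^{-\lambda_i (t - T)}, & t > T,
\end{cases}
$$

and multi-dose profiles are exact superpositions of shifted single-dose
solutions. Steady state under a repeated interval $\tau$ uses the geometric
accumulation factor $1/(1 - e^{-\lambda_i \tau})$; the peak is evaluated at
the end of the infusion and the trough at the end of the interval. The
closed form is verified in the test suite against independent numerical
integration of the ODE system (deSolve) to a relative $10^{-6}$ over
randomized parameter/regimen draws.

Numerical edge cases: a repeated root ($\alpha = \beta$, a measure-zero
configuration) is handled by a relative $10^{-9}$ epsilon split of the two
rates rather than a separate limit formula, keeping one code path; a
two-compartment model with $Q \to 0$ has a non-decaying peripheral term and
no finite accumulation limit, and is reported as a degenerate
(non-accumulating) error rather than returning an overflowing number.

## Population model

Individual parameters follow the standard nonlinear-mixed-effects (NLME)
construction $P_i = \theta_P \cdot \prod_j f_j(\text{cov}_i) \cdot
e^{\eta_{P,i}}$ with independent $\eta \sim N(0, \omega^2)$ (log-normal
between-subject variability, BSV). Continuous covariates enter as powers of
the normalized covariate — allometric weight scaling is
$(\text{WT}/70)^{k}$ — and categorical covariates as a multiplicative
fraction for the non-reference category. BSV is reported as %CV through the
exact log-normal relation $\omega^2 = \log(1 + (\text{CV}/100)^2)$, not the
small-variance approximation, so the round trip is exact.

The published final model shipped as `gentamicin_final_model()` is
two-compartment with $CL = 4.64\,(\text{WT}/70)^{0.71}$ L/h,
$V_c = 15.87\,(\text{WT}/70)^{0.93}$ L, $V_p = 4.11$ L, $Q = 0.62$ L/h, BSV
of 27.89 %CV on $CL$ and 37.80 %CV on $V_c$, and additive residual error
0.011 mg/L. Two reporting inconsistencies in the source required decisions:

* the clearance equation is printed once with coefficient 6 and elsewhere
  as 4.64 L/h at the 70-kg reference; 4.64 is consistent with the parameter
  table, its bootstrap interval and the narrative discussion, so 4.64 is
  the default (the coefficient is an ordinary model parameter and can be
  set to anything);
* the final additive error of 0.011 mg/L is implausibly small against the
  base model's 0.28 mg/L and the assay's <5% CV. This is the signature of a
  known degeneracy of designs with as many observations per subject as
  random effects (two observations, two etas): the marginal likelihood can
  grow along a $\sigma \to 0$ spike in which the residual model stops
  meaning anything. The package therefore (a) defaults its *simulation*
  residual to an assay-consistent 5% proportional error, and (b) bounds
  residual sigmas away from zero during estimation (defaults 0.005 mg/L
  additive, 1% proportional — several-fold below the assay scale).

$V_p$ and $Q$ carry no covariates in the final model; extrapolating those
70-kg-cohort-typical values to a 4.5-kg neonate is physiologically
questionable, so an optional allometric mode (`scale_vp_q = TRUE`: $V_p$
linear in weight, $Q$ with exponent 0.75) is provided for sensitivity
analysis. It is off by default to stay faithful to the reported model.

## Laplace marginal likelihood

The marginal likelihood is approximated per subject by Laplace's method
around the mode of the joint density $g(\eta)$ of (observations, random
effects): $-2\log L_i = 2g(\tilde\eta) - d\log 2\pi + \log\det H_i$. Three
implementation choices matter on sparse TDM data and are worth recording:

* **Mode search.** The per-subject mode is found by a vectorized damped
  Newton (Levenberg) iteration with finite-difference gradients and
  Hessians, run simultaneously over all subjects in compiled code. Sparse
  likelihood surfaces under sharp (5%) noise have narrow basins, so cold
  evaluations seed the search from both a coarse $\omega$-scaled eta grid
  and a per-subject least-squares inversion of the observations on the log
  scale, whose basin is far wider than that of the likelihood it seeds.
* **Two-mode mass.** With two observations and two random effects the
  subject posterior is not rarely bimodal, and a single-mode Laplace can
  miss up to $\log 2$ of mass per subject. Cold evaluations therefore run
  the mode search from the best start and the best well-separated
  runner-up and sum the two Laplace masses when distinct modes are found.
  This was validated against 64-node adaptive Gauss–Hermite quadrature,
  which also serves as the independent oracle in the test suite (agreement
  within 0.1 in $-2$LL on the toy fixtures).
* **Hessian validity.** A non-positive-definite Hessian at the end of a
  search means the iterate is not an interior mode; such contributions are
  penalized as invalid rather than evaluated (a floored determinant would
  otherwise turn $\log\det \to -\infty$ into an infinitely *good*
  likelihood, which the outer optimizer will happily chase).

The outer maximization runs `stats::nlminb` on transformed parameters
(log scale for positives, natural scale for power exponents) under box
constraints, with convergence declared at a relative $-2$LL change below
$10^{-8}$ (cap 500 iterations). Sparse designs use a deterministic "cold"
objective (modes recomputed from scratch each evaluation); rich designs
track warm-started modes for speed. PORT's "false convergence" exit —
expected on surfaces with small kinks where a subject's mode switches
branch — is re-verified by restarting at the solution until a restart no
longer improves the objective. De novo fits try three starts (a pooled
least-squares seed, the template values, and a data heuristic) and keep the
best optimum; standard errors come from a finite-difference Hessian of the
objective, delta-method-transformed to the natural scale. Initial values:
$\omega$ at 30 %CV and sigmas at assay scale where the template carries
zeros. Analytic standard errors are reliable on rich designs but can be
corrupted by mode-branch kinks on sparse peak/trough data; there, parameter
uncertainty should come from the bootstrap (which is also what the source
analysis reported).

## Stepwise covariate search

Forward addition requires a $-2$LL improvement above 6.64 ($\chi^2_1$,
$p = 0.01$); backward deletion removes any retained effect whose removal
worsens $-2$LL by less than 10.83 ($p = 0.001$). Candidates are weight,
age, serum creatinine (power on the cohort-median-normalized value) and sex
(fraction), on $CL$ and $V_c$. Ties break to the larger improvement, then
lexicographic effect name; failed candidate fits are skipped and logged.
Three safeguards make the deltas mean what they claim on kinked sparse
surfaces:

* candidate fits are multi-started from the null coefficient and from an
  *EBE regression* seed (slope of the parent's empirical Bayes etas on the
  covariate), the standard screening device;
* every $-2$LL difference is taken between the *best-known* fits of the two
  nested model classes, maintained in a cache — an optimization
  lucky-strike in one class cannot masquerade as a covariate effect;
* before an effect is accepted (or a removal judged), the opposite class is
  re-polished from the winning solution with the effect folded into the
  target's typical value and BSV (nested consistency).

During the search, continuous candidates are centered at the cohort median
(decorrelating exponent and typical value, whose 70-kg reference sits far
outside the pediatric weight range); selected weight effects are
re-referenced to the conventional 70 kg afterwards, an exact
reparameterization.

With the printed BSVs, assay-consistent noise, 22 subjects and one
peak/trough pair each, the marginal improvement of weight-on-$V_c$ given
weight-on-$CL$ concentrates near the 10.83 retention cutoff, so the
all-or-none selection of *both* weight effects is intrinsically variable
across replicate cohorts (roughly a coin flip for the $V_c$ term). The
source analysis reported a much larger improvement (61 points), which is
only reachable through the $\sigma \to 0$ degeneracy discussed above. The
package reports what the bounded-likelihood analysis supports.

## Model evaluation

The nonparametric bootstrap resamples subjects with replacement to the
original subject count, refits (warm-started from the reference estimates
for robustness), drops and counts failures (an error is raised above 50%),
and summarizes each parameter by the median and 2.5/97.5 percentiles of the
successful replicates. The visual predictive check simulates replicates of
the *exact* observed design — same subjects, covariates, dose histories and
sampling times, with BSV and residual error — and compares observed
5/50/95th percentiles per observation class with the simulated quantiles
and their 95% bands. Stratification is by class (peak vs trough), not time
bins: a design with exactly two nominal sampling classes makes continuous
binning meaningless. Both are bit-reproducible given their seed.

## Monte Carlo dosing simulation

Four pediatric age groups with CDC 50th-percentile boys' weights — neonate
(1 month, 4.5 kg), infant (6 months, 7.9 kg), toddler (18 months, 11.5 kg),
child (7 years, 22.9 kg), all overridable — receive once-daily doses of
2–8 mg/kg (step 0.5) as 1-h infusions. Per scenario, 1000 virtual subjects
are drawn from the model's BSV (no residual error: the target concerns true
exposure) and evaluated with the closed-form steady-state solution; the
same eta draws are reused across the dose and MIC grids (common random
numbers), which makes PTA *exactly* non-decreasing in dose and
non-increasing in MIC. The efficacy target is a peak-to-MIC ratio of 10
over MICs 0.5–2 mg/L with attainment declared at PTA ≥ 90%; the safety
screen is a median steady-state trough below 1 mg/L. Recommended dose
ranges start at the minimum attaining, trough-safe dose and extend through
the largest contiguous trough-safe dose in the grid.

The phrase defining the target ("$C_{max}$/MIC target of 10 mg/L")
conflates a dimensionless ratio with a concentration. Both readings are
implemented (`pta_config(mode = "ratio")`, the default, and
`mode = "fixed_cmax"`, i.e. $C_{max} \ge 10$ mg/L regardless of MIC). The
choice matters: a 4.5-kg neonate at 7 mg/kg has a median steady-state peak
of ~16 mg/L, so under the ratio reading MIC 2 mg/L is unattainable within
the 2–8 mg/kg grid, whereas the published recommendation (6–7 mg/kg at MIC
2) is consistent with the fixed-concentration reading. The published
minimum-dose table is therefore treated as an interpretation-dependent
output, not a reproducible number; the package's contract is the complete
grid, the sensitivity switch, and the monotonicity/safety/reproducibility
properties.

## Synthetic cohort generator

The generator emulates the statistical structure of the study cohort so
that every pipeline stage is testable without the (unavailable) original
data.

* **Ages.** The printed age summary (34.88 ± 31.9 months on 1–72) has an SD
  *larger than a uniform distribution on that range* (20.5), which forces a
  strongly bimodal cohort — mostly infants plus a group of older children.
  Ages are drawn from a two-component truncated-normal mixture
  (52.5% at 3.5 ± 2.5 months, 47.5% at 70 ± 4 months, both truncated to
  1–72), calibrated so the generated mean and SD converge to the printed
  summaries.
* **Weight.** A monotone CDC-like growth curve $4.52 \cdot
  \text{age}^{0.30}$ kg with log-normal scatter (38% CV), rejection-
  truncated to 3.98–17.7 kg. The coefficient is calibrated so the truncated
  cohort mean converges to the printed 10.13 kg. The scatter share is
  deliberately substantial: weight is the covariate that actually drives
  the generated kinetics, and it must remain statistically separable from
  age for covariate-selection studies to be meaningful — mirroring the
  source analysis, in which weight, not age, was retained. A
  near-deterministic growth curve would make the two indistinguishable at
  $n = 22$ (age would carry >90% of the weight signal). The cost of this
  choice is a generated weight SD of ~3.9 kg against the printed 5.25 kg;
  matching that SD under a monotone curve would force age–weight
  correlation ≈ 0.95 and an unidentifiable covariate problem, so the mean
  (which is also the externally checked quantity) takes precedence.
* **Serum creatinine** is uniform on 0.27–0.51 mg/dL; the printed SD of
  0.82 contradicts its own range and is treated as a typo.
* **Dose and interval.** Dose per administration is truncated-normal
  2.26 ± 0.33 (1.78–2.73) mg/kg. The printed interval summary "8 (8–12)" is
  a median with interquartile range, so the 12-h fraction defaults to 1/3 —
  the simplest value reproducing both printed quartiles (median 8, upper
  quartile 12).
* **Sampling.** 30-minute infusions; one peak and one trough per subject.
  The source sentence on peak timing is garbled ("measured half an hour at
  the end of a 30-min infusion"); the package reads it as half an hour
  *after the end* of the infusion (1.0 h after dose start), standard
  aminoglycoside TDM practice, and exposes the offset as
  `sampling_design(peak_offset = )`.
* **Observation noise** defaults to 5% proportional (the assay's CV bound),
  not the degenerate printed 0.011 mg/L additive error.

What passing tests on these cohorts do *not* show: the generator has clean
steady dosing histories, no missingness, no recording-time error, no
critically-ill physiology and no nephrotoxic co-medication; real TDM data
are messier in all five ways.

Posterior-predictive simulation of the observed design under the final
model reproduces the printed mean peak (5.45 mg/L) within ~2%, but
over-predicts the printed mean trough (0.58 mg/L) by ~18%: the unscaled
$V_p/Q$ of the final model give a 10-kg child a terminal half-life of
~7.6 h, slower than the observed troughs imply (the allometric sensitivity
mode errs in the other direction, ~0.3 mg/L). The package reports this
tension rather than adjusting either model or generator to hide it.

## Problem sizes and tolerances used by the test suite

Structural-oracle equivalence uses 100 randomized scenarios at relative
$10^{-6}$; quadrature-oracle equivalence uses 2–3-subject toys at the assay
noise scale within 0.1 in $-2$LL; parameter recovery fits 20 replicate
200-subject, 8-sample datasets (allometric exponents fixed at their
published values — estimating an exponent from weights confined to
3.98–17.7 kg propagates its noise through a ~1.9-unit log lever arm to the
70-kg reference and is not how a known allometric model is used);
selection-power runs 20 replicate 22-subject cohorts at screening-grade
optimizer settings; posterior-predictive checks use 1000 replicate cohorts;
the dosing grid uses the full default configuration (4 groups × 13 doses ×
3 MICs × 1000 subjects). Bootstrap and VPC are exercised at reduced
replicate counts (tens to low hundreds); their production defaults are 1000.

## Known limitations

One- and two-compartment IV models only (no absorption, no saturable
elimination, no three-compartment extension); diagonal $\Omega$ restricted
to $CL$ and $V_c$ by default; no renal-maturation or post-menstrual-age
functions; power/fraction covariate forms only; no prediction-corrected
VPC; no MIC-distribution-weighted cumulative response. The Laplace
approximation degrades on sparse subjects whose posterior is strongly
non-Gaussian; the two-mode extension captures the dominant bimodal cases
but triple-or-more-modal posteriors are approximated by their best two
modes.
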
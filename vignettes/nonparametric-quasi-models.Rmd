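---
title: "Nonparametric population PK estimation and artificial quasi-models"
author: "npqm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonparametric population PK estimation and artificial quasi-models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npqm)
```

## The modeling problem

Therapeutic drug monitoring of beta-lactams such as piperacillin in
intensive care has to individualize dosing from very little data: a handful
of measured concentrations per patient, and population priors built from
cohorts that are often no larger than a dozen subjects. `npqm` implements
the nonparametric route to this problem end to end:

1. a **structural model** predicting concentrations from PK parameters
   under the patient's infusion history;
2. an **observation (error) model** translating a predicted concentration
   into the standard deviation of its measurement;
3. a **population model**: a discrete mixing distribution over parameter
   space, estimated by nonparametric maximum likelihood on an adaptive
   grid;
4. **individual estimation**: MAP Bayesian reweighting of a discrete prior
   by one subject's data;
5. **quasi-models**: fully artificial discrete priors — uniform random
   support points with equal probabilities — that can stand in for the
   population model, plus per-subject selection of the best quasi-model by
   prediction MSE.

All interfaces use concentrations in mg/L, times in hours, volumes in L,
rate constants in 1/h and creatinine clearance in mL/min.

## Structural models and their assumptions

The one-compartment model treats the body as a single well-stirred volume
`V` with first-order elimination `K`; the two-compartment model adds a
peripheral space exchanging with the central volume `Vc` through the
micro rate constants `KCP` and `KPC`. Both are linear, so an arbitrary
multi-dose history is handled by exact superposition of single-infusion
solutions — there is no steady-state shortcut, and overlapping infusions
are legal. For a constant-rate infusion the one-compartment solution is

$$c(t) = \frac{R_0}{KV}\left(1 - e^{-K t_e}\right) e^{-K t_w},$$

with \(t_e\) the time spent inside the infusion window and \(t_w\) the
washout time; the two-compartment solution is the analogous bi-exponential
in the eigenvalues \(\alpha, \beta\) of the rate matrix. When the
eigenvalues coincide within a relative gap of `1e-10` the critically
damped (l'Hôpital) limiting form is used rather than failing; with
`KCP = 0` the model reduces *exactly* to the one-compartment form. The
closed forms are verified in the test suite against an independent
matrix-exponential propagator over 200 random parameter/regimen draws at a
relative tolerance of 1e-6.

Renal elimination can be driven by creatinine clearance through
`K = KI + KS × CRCL`. Two conventions had to be fixed because they are
frequently left implicit:

* **CRCL scale.** `effective_K()` consumes CRCL in **mL/min**. With the
  packaged ranges (KS up to 0.006 1/h per mL/min) a patient at
  100 mL/min spans the same elimination range as the covariate-free model,
  which is the consistency check behind the choice.
* **Time base of the clearance equation.** Jelliffe's unstable-renal
  mass balance contains the factor 1440 min/day, so the interval between
  the two serum creatinine samples is taken in **days**
  (`hours_to_days()` converts). The adjusted daily creatinine production
  `P_adj` uses the classic sex-specific, age-linear, weight-proportional
  constants, exposed wholesale in `jelliffe_production_constants()` so a
  site can substitute its own table.

The number of infusions a patient received *before* the sampled one is a
regimen-builder argument (`piperacillin_regimen(n_prior_doses = 4)`,
i.e. ≥ 24 h of q6h therapy) because it is patient-history dependent;
within a fitting window CRCL is treated as constant — time-varying renal
function is out of scope.

## The observation model

Replicate calibration measurements give (concentration, SD) pairs;
`fit_error_polynomial()` fits unweighted polynomials of degree 1–3 and
flags the highest-r² fit. The packaged piperacillin HPLC-UV cubic
(`piperacillin_error_poly()`) is monotone increasing on c ≥ 0, so its
intercept 0.255 mg/L is a global SD floor. Evaluation outside the
calibrated range is allowed (it errors only on a nonpositive SD, which
signals genuine misuse).

Clinical dosing software additionally knows dosing, model-misspecification
and sample-timing error settings. Their exact internal semantics are not
public, so `observation_variance()` composes them as proportional SD terms
added in quadrature,

$$\mathrm{var}(c) = \gamma^2\left[SD(c)^2 + (0.01c)^2 + (0.01c)^2 + (0.01c)^2\right],$$

a package convention that is documented as such and switchable off
(`noise = NULL`), keeping the pure assay polynomial testable in isolation.
Population fits default to the pure polynomial.

## Nonparametric maximum likelihood on an adaptive grid

The population distribution is a discrete mixture
\(F = \{(\theta_j, w_j)\}\). For a fixed grid, the weights maximizing
\(\sum_i \log \sum_j w_j L_{ij}\) are found by the multiplicative EM
update \(w_j \leftarrow w_j\,\mathrm{mean}_i(L_{ij}/(Lw)_i)\), which is
monotone in the log-likelihood by construction; the test suite checks its
optima against exhaustive simplex grid search on small problems. All
likelihoods are computed in log space and row-rescaled by their maximum,
with the scaling constants carried separately, so no subject can underflow.

The grid itself evolves by cycles of

* **weighting** (EM as above, from uniform),
* **condensation** — three rules:
  (i) drop weights below `1e-8` of the maximum;
  (ii) merge points closer, in every coordinate, than the *current working
  resolution* (a quarter of the active perturbation size, floored at
  `1e-4` of each parameter range) — with a fixed fine tolerance,
  near-duplicates at the working scale split their weight and evade the
  relative drop rule, inflating the grid by orders of magnitude;
  (iii) purge points whose simplex directional derivative
  \(D_j = \mathrm{mean}_i(L_{ij}/(Lw)_i)\) is below \(1 - 10^{-6}\): at the
  NPML optimum \(D_j = 1\) exactly on the support and \(< 1\) elsewhere,
  and this first-order criterion removes in one step the off-support
  points whose weight EM only decays geometrically slowly;
* **refinement** — every surviving point is perturbed by ±Δ along each
  axis *and each pair diagonal*, clipped to the parameter box. Axis moves
  alone provably stall on coordinate-wise saddle points, which arise
  naturally here because parameters such as K and V are strongly
  correlated through the predicted curve.

Δ starts at 20% of each range. When a cycle's log-likelihood gain falls
below `tol` (default 0.01), Δ contracts by `refinement_shrink` (default
0.5); the fit terminates when a stalled cycle finds Δ already at its floor
`delta_min` (default `1e-4` of range), or at `max_cycles` (default 400).
Contraction-on-stall rather than contraction-every-cycle is what lets the
grid travel along curved likelihood ridges: a fixed shrink schedule
exhausts its total step budget before reaching the optimum. The initial
grid is a Halton low-discrepancy set with a seeded uniform shift, so fits
are fully reproducible from `(seed, config)`.

Numerical tolerances worth knowing: zero-noise recovery exercises (used in
the tests) run at `tol = 1e-4`, `delta_min = 1e-6` because within 1%
of a noise-free truth the log-likelihood surface is nearly flat
(< 0.15 units), so the default tolerance is "converged" in likelihood
terms before reaching 1% parameter resolution. That is a solver setting,
not a change of the data-generating conditions.

### Fit diagnostics

`fit_metrics()` reports −2 log-likelihood; the **small-sample-corrected**
AIC \( -2LL + 2P + 2P(P+1)/(N-P-1)\) and BIC \(-2LL + P\ln N\) with
\(P\) = number of random-effect parameters + 1 error parameter (the
correction is used because it reproduces the reference piperacillin model
comparison to the printed decimal; this inference is deliberate and
documented); weighted prediction errors
\((c_{obs} - c_{pred,pop})/SD(c_{pred,pop})\) summarized as bias (mean)
and imprecision (bias-adjusted mean square); observed-vs-predicted OLS
regressions under both population (prior-weighted) and posterior
(individually reweighted) predictions; and per-parameter shrinkage.
Shrinkage has no universal nonparametric definition, so the package states
its own: `100 × mean over subjects of the posterior variance / population
variance` of each parameter — values near 0 mean the data dominate the
prior, values near 100 mean the posterior collapses onto it.

## Individual MAP Bayesian estimation

`posterior()` applies Bayes' rule on the discrete prior:
\(w_j^{post} \propto w_j L_j\). The fitted curve is the posterior-weighted
average of the per-point predicted curves — a deliberate choice, because
artificial priors legitimately spread posterior mass over several support
points, and a single-point curve would misrepresent that. Both the MAP
point (maximal posterior weight, ties to the first index) and the
posterior mean are always reported; which one a workflow treats as "the"
estimate is a configuration switch (`estimate` in the run config), since
neither is canonically preferred.

`compare_estimates()` implements the ratio conventions used to compare two
estimation routes subject by subject: MSE ratio (0.01–1.00 = the first
route predicts better, 1.00 = equivalence, > 1.00 = the second is better),
elementwise parameter ratios, and for two-compartment fits the ratio of
KCP/KPC ratios.

## Quasi-models

A quasi-model is a fully artificial prior: `n_points` support points drawn
uniformly within the declared parameter ranges — one independent uniform
stream per parameter, point *j* pairing the *j*-th draw of every stream —
all with probability `1/n_points`. The default 399 reflects the support
cap of the clinical software the construction was designed around and is a
default here, not a limit; the default generation bounds are the packaged
posterior ranges, because the stated methodology generates quasi-models
inside the parameter space established by population modeling. Per-model
seeds in a batch are derived reproducibly from one master seed.

`select_best()` runs the MAP Bayesian step for every model of a batch
against one subject and keeps the lowest-MSE model (ties to the lowest
index, so selection is order-invariant and deterministic). Note the
honest caveat inherited from the methodology: the data used to *select*
the best quasi-model are the same data used to *evaluate* it; there is no
held-out set at n = 1. Best-of-batch MSE is therefore an optimistic
estimate of predictive performance.

## The synthetic-data generator

`generate_cohort()` emulates the reference rich-sampling design: 12
subjects, 4000 mg infused over 3 h every 6 h, four prior doses plus the
sampled one, six samples at 0.25/0.5/1/1.5/2/2.5 h after the end of the
last infusion (72 observations in all), truth drawn uniformly within the
declared ranges, and observational noise `Normal(0, SD(pred))` from the
assay polynomial. Negative draws are truncated at zero and counted
(`n_truncated`) — the simplest auditable rule for a strictly nonnegative
measurand. The covariate variant draws a per-subject CRCL (default
uniform on 30–150 mL/min, a plausible ICU span) and eliminates with
`K = KI + KS × CRCL`.

What the generator does **not** emulate: assay failures and missed draws,
time-varying renal function, non-uniform (e.g. multimodal) population
distributions unless configured, correlation between parameters and
covariates beyond the CRCL mechanism, and recording errors in dose or
sampling times. A green recovery test therefore establishes correctness of
the estimation machinery under the stated design, not robustness to
clinical data pathologies.

## Known limitations

* The weight optimizer is EM, not the primal-dual interior-point method of
  the original NPAG software; equivalence is at the level of optima (and is
  tested), not iterates or runtimes.
* One- and two-compartment IV-infusion models only; no absorption or
  nonlinear elimination.
* Single constant covariate (CRCL) per fitting window; no covariate search
  automation.
* The MSE-based quasi-model selection reuses its selection data, as noted
  above.
* Bias/imprecision are computed against population predictions, which on
  heterogeneous cohorts are dominated by between-subject variability; they
  are comparative diagnostics across models on the same data, not absolute
  measures of assay-scale misfit.
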
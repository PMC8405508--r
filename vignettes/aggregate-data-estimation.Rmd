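---
title: "Estimating population PK models from aggregate data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating population PK models from aggregate data: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggpk)
```

## The problem

Population pharmacokinetic analysis normally requires individual-level
concentration measurements. In model-based meta-analysis, however, the
available information is often *aggregate*: the mean concentration at each
sampling time and, at best, the variance–covariance matrix of the
observations across subjects. `aggpk` implements maximum-likelihood
estimation of full nonlinear mixed-effects (NLME) models — fixed effects,
random-effect variances and residual variances — from exactly this kind of
summary data, together with the matching individual-data FO/FOCE(I)
likelihoods, expected Fisher information for optimal design, and a
deterministic replacement for stochastic simulation-and-estimation (SSE).

## Model and likelihood

A subject's observation vector is
$y_i = f(\theta_i, \xi) + h(\theta_i, \xi, \varepsilon_i)$, with structural
model $f$, residual model $h$ (additive, proportional or combined),
individual parameters $\theta_i = g(\beta, b_i)$ (lognormal by default,
$\theta_i = \beta e^{b_i}$), and random effects $b_i \sim N(0, \Omega)$.
The aggregate data are the observed mean vector $\bar y$ and the
variance–covariance matrix $V$ of the $N$ subjects' observations, with the
**population covariance convention** (denominator $N$, not $N-1$). The
aggregate log-likelihood is

$$
\log L(\bar y, V \mid \Psi) = -\tfrac{N}{2}\left[
  \mathrm{tr}(V \tilde V^{-1})
  + (\bar y - \tilde y)^\top \tilde V^{-1} (\bar y - \tilde y)
  + \log |\tilde V| \right],
$$

where $(\tilde y, \tilde V)$ are the model-expected moments. Three
approximations of the moments are provided:

* **FO** — linearization at $b = 0$:
  $\tilde y = f(g(\beta, 0))$,
  $\tilde V = J \Omega J^\top + \mathrm{diag}(\text{residual variances})$,
  $J = \partial f / \partial b |_{b=0}$.
* **FOCE / FOCEI** — a quasi-Monte-Carlo average of the conditional
  linearization over Sobol-sampled random-effect vectors; FOCEI evaluates
  the residual-error magnitude at the simulated individual predictions
  ("interaction"), FOCE at the typical prediction.
* **MC** — moments of the residual-free simulated predictions plus the
  average diagonal residual term; asymptotically exact for symmetric
  residual distributions.

Two conventions matter for comparability with the standard pharmacometric
objective function: no $2\pi$ constants appear anywhere (so
$\mathrm{OFV} = -2 \log L$ matches the NONMEM-style values), and the
residual contribution to $\tilde V$ is diagonal (residuals independent
across observations). With the $1/N$ covariance convention, the FO
aggregate log-likelihood is *algebraically identical* to the sum of
per-subject FO log-likelihoods — the package's test suite verifies this
identity to $10^{-8}$ and the classical worked one-compartment example
(OFV 0.0258 additive / 39.2132 proportional) to the printed precision.
With $N = 1$ and $V = 0$ the aggregate expression collapses to the
individual-data log-likelihood exactly.

## Quasi-Monte-Carlo integration

FOCE- and MC-aggregate moments integrate over the random-effect
distribution with a Sobol low-discrepancy sequence (Gray-code construction,
Joe–Kuo direction numbers, dimensions up to 10). The sequence is built into
the package; points are mapped through the inverse normal CDF and scaled by
a symmetric square root of $\Omega$, and the all-zero leading point is
skipped. The default sample size is `max(300, N)`. The adequacy of 300
points is checked the way the method's diagnostic prescribes: leave each
sampled vector out in turn, recompute the aggregate log-likelihood, and
divide the SD of the leave-one-out values by the number of subjects
(`loo_mc_se()`). For the built-in two-compartment study conditions this
per-subject error is of order $10^{-3}$ — small against the likelihood
differences that drive estimation.

During estimation the *same* standard-normal Sobol points are kept fixed
across all candidate parameter values and re-scaled to each candidate
$\Omega$ (common random numbers), so the objective is deterministic and
smooth enough for quasi-Newton polishing.

## Built-in models and study conditions

* `wang` — one-compartment decay $f = 10 e^{-\theta t}$, one lognormal
  random effect ($\beta_1 = 0.5$, $\omega^2 = 0.04$, $\sigma^2 = 0.1$ in
  the classical configuration).
* `twocomp_oral` — two-compartment first-order absorption model,
  parameters (CL, Vc, Vp, Q, ka) = (5 L/h, 10 L, 30 L, 10 L/h, 1/h) in the
  reference configuration, lognormal IIV with log-SD 0.3 on all five,
  additive residual SD 0.2 mg/L, 100 mg dose, sampling at 0.1, 0.25, 0.5,
  1, 2, 3, 5, 8, 12 h. Evaluated in closed form via the bi-exponential
  disposition constants, vectorized across parameter draws; degenerate
  coincidences of ka with a disposition eigenvalue are lifted by a
  $10^{-10}$ relative perturbation of ka. Correctness is guarded by an
  adaptive-ODE oracle test at $10^{-8}$ relative error.
* `transit2` — transit-compartment absorption over the same disposition,
  parameters (MTT, CL, Vc, Vp, Q). The transit chain is interpreted as
  depot → transit₁ → transit₂ → central with all three steps at rate
  $k_{tr} = (n+1)/\mathrm{MTT} = 3/\mathrm{MTT}$ — i.e. an Erlang-3 input
  — convolved in closed form with the disposition. The competing
  convention $k_{tr} = n/\mathrm{MTT}$ (depot outside the chain) would
  rescale MTT by 2/3; the $(n+1)$ convention was chosen because it makes
  MTT the literal mean transit time of the whole absorption path.

The misspecified-design study pairs a `transit2` *generator* (MTT 1 h,
lognormal IIV log-SD 0.3 **on MTT only**, disposition fixed, 100 mg dose)
with the `twocomp_oral` *analytic* model. The generator deliberately
carries no disposition IIV: the transit-compartment count, the natural
second source of absorption variability, is structurally fixed at 2 here
(a continuous-n chain cannot be expressed as an integer cascade), so the
variability the analytic model must absorb is confined to absorption.
The generator dose is taken equal to the analytic study's 100 mg.

## Estimation

`fit_model()` maximizes the selected log-likelihood over a transformed
parameter space: log scale for positive fixed effects and all variance
terms; $\Omega$ off-diagonals are held fixed (none of the built-in studies
estimates correlations). The optimizer is a derivative-free Nelder–Mead
stage followed by a BFGS polish (relative tolerance $10^{-10}$).

Two safeguards keep the quasi-MC objectives inside their region of
validity:

* a smooth quadratic barrier beyond a wide box ($e^{\pm 9}$, about four
  orders of magnitude each way around the start), and
* staged estimation (`fo_prestart`, default on): FOCE/MC-aggregate fits
  start from a preliminary FO-aggregate fit of the same data.

The rationale: far from plausible values — in particular at very large
random-effect variances — the integrand over $b$ becomes so heavy-tailed
that a fixed 300-point Sobol sample cannot resolve it, and the resulting
finite-sample objective develops spurious optima that move with the sample
rather than the data. Staging from FO (itself exactly aggregate-equivalent)
and bounding the search keeps the fits where the approximation error is
controlled; it is also the field's standard workflow for conditional
methods. Both safeguards can be changed via `control`.

A candidate covariance that fails its Cholesky factorization is penalized
with $-10^{10}$ minus the magnitude of the most negative eigenvalue, so the
optimizer sees a finite, repulsive surface rather than an error.

Standard errors come from the central-difference Hessian of the negative
log-likelihood on the natural (reported) parameter scale, with one
Richardson refinement; `rse_percent` is $100 \cdot \mathrm{SE}/|\hat\psi|$.

## Optimal design and the SSE replacement

`expected_fim()` simulates the *expected* aggregate data from a generating
model under a chosen moments approximation, then takes the negative
numerical Hessian of the aggregate log-likelihood with respect to the
analytic model's parameters. Under FO this equals the classical linearized
population Fisher information — the package carries an independent oracle
(`fo_fim_linearized()`, the textbook gradient-assembled FIM) and the two
agree entrywise to better than 0.1% on the built-in models. Because the
generating and analytic models need not coincide, the same mechanism gives
expected information under model misspecification, where classical optimal
design expressions do not apply.

`aggregate_od()` is the one-step SSE replacement: simulate the expected
aggregate data once (MC approximation by default — the data distribution's
true moments), fit the analytic model to it, attach Hessian-based expected
SEs. `run_sse()` provides the conventional replication loop (simulate
individual data, optionally aggregate, fit by each method, summarize) for
comparison; replicate seeds derive from a master seed by a counter and
failed replicates are excluded from summaries with counts reported.

## Numerical choices, problem sizes, and limitations

* Finite-difference random-effect Jacobians use central differences with
  step $10^{-5} \max(1, |b_j|)$. The FIM oracle's moment gradients use
  relative step $10^{-4}$ with Richardson refinement; substantially smaller
  steps amplify the inner Jacobian's rounding noise instead of reducing
  truncation error.
* The test suite exercises the full study conditions at reduced problem
  sizes chosen to keep the whole suite in the minutes range: parameter
  recovery uses one 3000-subject dataset with a 3000-point quasi-MC sample;
  the SSE-versus-OD comparison uses 50 replicates of 100 subjects; the
  leave-one-out diagnostic uses 1000 subjects and 300 points. These sizes
  reproduce the qualitative and quantitative behaviour of the method at
  the cost of wider Monte-Carlo bands than a production study would use.
* The synthetic-data generator draws lognormal individual parameters and
  normal residuals on a balanced design — exactly the assumptions of the
  aggregate likelihood. Passing tests therefore demonstrate internal
  correctness and the published identities, not robustness to the ways
  real data violate those assumptions (unbalanced sampling, BLQ censoring,
  non-normal random effects, covariate structure), none of which the
  aggregate expressions here cover.
* Individual-data FOCE/FOCEI for *proportional* error depends on
  conventions for the inner (MAP) objective that differ between
  implementations; this package evaluates the residual variance at the
  candidate individual prediction inside the MAP step. Its individual
  FOCE(I) proportional objective values therefore differ from NONMEM-type
  references at the second decimal, while the additive-error values and
  all aggregate-data values match the published ones. The aggregate
  FOCE(I) method needs no MAP step at all.
* Covariates, inter-occasion variability, multi-dose regimens and
  multi-response models are out of scope; the model contract allows custom
  structural models via `structural_model()`.

## Reproducing the headline diagnostic

```{r loo, eval = FALSE}
model <- pk_model("twocomp_oral")
params <- pop_params(c(CL = 5, Vc = 10, Vp = 30, Q = 10, ka = 1),
                     omega = rep(0.3^2, 5), sigma_add2 = 0.2^2)
design <- pk_design(c(0.1, 0.25, 0.5, 1, 2, 3, 5, 8, 12),
                    dose_amount = 100, n_subjects = 1000)
agg <- aggregate_observed(simulate_individuals(model, params, design, seed = 1))
loo_mc_se(agg, model, params, design, approximation = "mc",
          n_sim = 300)$se_per_subject
```

`scripts/acceptance.R` runs exactly this computation from the command line
and writes the result as JSON.
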
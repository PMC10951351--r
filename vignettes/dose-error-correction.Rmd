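---
title: "Correcting shared and unshared dose measurement error in grouped excess-relative-risk regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting shared and unshared dose measurement error in grouped excess-relative-risk regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doserr)
```

## The problem

Radiation-epidemiology risk models are usually fitted to grouped data:
cancer case counts and person-year offsets cross-classified by dose group,
with a linear or linear-quadratic excess relative risk (ERR),

$$\lambda_g = O_g\,e^{\kappa}\,\bigl(1 + \alpha d_g + \beta d_g^2\bigr).$$

Dose estimates carry measurement error of two canonical kinds. *Berkson*
error means the true dose scatters around the assigned value; *classical*
error means the observed (surrogate) dose scatters around the truth and
attenuates fitted slopes. Each kind can be *shared* across a whole cohort
(dosimetry-system biases) or *unshared* (per-person). Shared error is the
hard case: it does not average out, it correlates everyone's errors, and it
can masquerade as (or hide) curvature in the dose response.

`doserr` is a simulation laboratory for this setting. It generates
synthetic cohorts whose doses carry configurable shared/unshared
Berkson/classical lognormal errors, fits the grouped ERR model by six
estimators, and measures coverage probability of their 95% intervals and
the percent bias of the predicted ERR.

## The error model

For individual $i$ in dose group $k_i$ and sub-simulation $j$,

$$D_{\mathrm{true},i,j} = D_{\mathrm{cent},k_i}
  \exp\!\bigl[-\tfrac12(\sigma^2_{sB}+\sigma^2_{uB})\bigr]
  \exp\!\bigl[\sigma_{sB}\,\varepsilon_j + \sigma_{uB}\,\delta_{i,j}\bigr],$$

and the surrogate dose is built identically from the classical magnitudes
$(\sigma_{sC},\sigma_{uC})$ with its own shared ($\mu_j$) and unshared
($\kappa_{i,j}$) standard-normal fields. The leading factor makes the
theoretical mean of every dose equal its group's central estimate. The
four magnitudes are log-scale SDs ("geometric SDs": 0.2 means 20%); setting
the Berkson pair to zero leaves a purely classical model and vice versa.
Between-individual correlation of true doses is
$(e^{\sigma_{sB}^2}-1)/(e^{\sigma_{sB}^2+\sigma_{uB}^2}-1)$
(`analytic_dose_correlation()`), which the sampled estimator
`dose_correlation()` reproduces.

Each of the four fields draws from its own named random-number stream
derived from the ensemble seed (`derive_seed()`), so changing one magnitude
never perturbs the other components' draws; this is what makes the
classical-error-invariance properties exact rather than statistical. A
zero-magnitude field is skipped without consuming draws, which is
equivalent (its values would be multiplied by zero) and makes zero-error
scenarios cheap.

## The synthetic cohort

One *meta-simulation ensemble* (`build_ensemble()`) is: $m$ sub-simulated
dose realizations; per-individual mean relative risks
$\tfrac1m\sum_j (1+\alpha D_{ij}+\beta D_{ij}^2)$; a multinomial draw of
$N$ cases over groups with person-year-weighted probabilities (held fixed
across the $m$ sub-simulations); and the per-group mean-dose vectors the
estimators consume. Defaults are the reference study
conditions: $m = 1000$, $N = 250$, dose groups 0–0.07, 0.08–0.19,
0.20–0.99, 1.00–2.49 and 2.50+ Gy with central doses 0.03, 0.12, 0.5, 1.5
and 2 Gy, and risk models $\alpha = 0.25$/Gy, $\beta = 2$/Gy$^2$
(linear-quadratic) or $\alpha = 3$/Gy (linear).

Two design points were genuinely open and are package choices:

* **Cohort composition.** The person-year distribution and most central
  doses behind the reference tables are not fully determined, so they are
  configuration here. The package defaults to 10,000 individuals split
  70/15/10/4/1% across the five groups (person-years proportional), a
  low-dose-heavy shape typical of the Life Span Study leukaemia data; the
  top-group central dose is 2 Gy, the others are placed near plausible
  person-year-weighted group means. All of this is configurable
  (`dose_group_spec()`), and the quantities the test suite verifies
  against reference values were chosen to be insensitive to it
  (zero-error coverage, analytic correlations, coefficient-to-bias
  arithmetic).
* **Mean relative risk.** We average the relative risk over
  sub-simulations (the expectation of RR), not the RR of the averaged
  dose; the two coincide for the linear term and differ slightly in the
  quadratic term.
* **The unadjusted dose vector.** Averaging surrogate doses over all $m$
  sub-simulations would cancel the shared classical error entirely, which
  would contradict the known degradation of unadjusted coverage under
  classical error. The designated unadjusted vector is therefore
  sub-simulation 1's surrogate group means. With groups this large the
  unshared classical part averages out within groups, so the unadjusted
  dose is approximately $D_{\mathrm{cent}}e^{\sigma_{sC}\mu_1 -
  \sigma_{sC}^2/2}$; for the linear model this predicts a mean fitted
  slope of about $\alpha\,e^{\sigma_{sC}^2}$ — with 20% shared classical
  error, $3\,e^{0.04}\approx 3.12$ — and coverage near 82%, both of which
  the test suite confirms empirically.

## Fitting machinery

`fit_mle()` maximizes the grouped Poisson likelihood with the relative
risk constrained positive. $\kappa$ is profiled out in closed form
($e^{\hat\kappa} = N / \sum_g O_g r_g$), leaving a 2-D (or 1-D) problem
solved by damped Newton iteration with analytic gradient and Hessian,
multi-start (the origin, a least-squares moment guess, and a unit point),
and a golden-section fallback plus coordinate polish for non-concave
corners; convergence requires either a small gradient or a Newton
decrement below $10^{-8}(1+|\ell|)$, which is the attainable resolution of
the log-likelihood in double precision. Profile 95% intervals
(`profile_ci()`) bisect the profile deviance to the $\chi^2_1$ threshold
(3.841); a side that hits the positivity boundary first is reported at the
boundary and flagged, a side that never reaches the threshold is reported
open. The batched versions of the fit and intervals are implemented in
C++ because frequentist model averaging refits every one of the $m$ dose
vectors.

The AIC counts $\kappa$ as a free parameter (3 parameters for the
linear-quadratic form, 2 for the linear); only AIC *differences* enter the
model-averaging weights, so the likelihood-constant convention (full
Poisson density including $-\log y!$) is immaterial and is asserted as
such by the offset-equivariance and shift tests.

## The six estimators

* **Unadjusted** regression uses the designated surrogate vector — the
  only estimator that sees classical error.
* **Regression calibration (RC)** fits the across-realization mean of the
  true-dose group means (the conditional expectation of true dose).
* **Extended regression calibration (ERC)** keeps the RC point estimate
  and widens its profile interval for shared dose uncertainty: every dose
  realization is refitted, the between-realization coefficient variance is
  combined with the within-fit profile variance (law of total variance),
  and both interval arms are scaled by
  $\sqrt{1 + \mathrm{Var}_{\mathrm{between}}/\mathrm{SD}^2_{\mathrm{within}}}$.
  This construction is a documented stand-in chosen to satisfy the
  observable ERC constraints — exact reduction to RC at zero Berkson
  error, strictly wider intervals under shared Berkson error — while the
  original method's internals live in a companion publication; it is
  isolated behind its method tag so a faithful replacement can drop in,
  and nothing the package verifies against published values depends on
  ERC behaviour at non-zero Berkson error.
* **Monte Carlo maximum likelihood (MCML)** maximizes
  $\log\frac1m\sum_k L_k(\theta)$ — the average of likelihoods, not of
  log-likelihoods — with profile intervals on the same Monte-Carlo
  averaged likelihood (log-sum-exp throughout).
* **Quasi-2DMC with Bayesian model averaging** places a softmax
  distribution $p_j(\lambda)$ over the $m$ dose vectors
  (`softmax_probs()`), so the posterior is the mixture
  $\sum_k p(\alpha,\beta,\kappa \mid Y, D_k)\,p_k$, and samples it by
  alternating Metropolis–Hastings sweeps: $\kappa,\alpha,\beta$ one at a
  time by random-walk proposals against the mixture likelihood
  (`mixture_log_likelihood()`) times N(0, 1000²) priors, then the
  $\lambda$'s in consecutive blocks of 10 with one joint accept per block.
  Proposal SDs are 0.2 ($\kappa$), 1 ($\alpha,\beta$) and 2 ($\lambda$);
  two chains run 1000 burn-in plus 1000 retained iterations; the summary
  is the pooled posterior mean with equal-tail 2.5/97.5% intervals, with
  per-parameter Brooks–Gelman–Rubin statistics (`bgr_statistic()`) and
  acceptance rates always reported. Chain 2 starts two proposal-SDs away
  from chain 1 on each coefficient. Per-vector log-likelihood terms are
  cached within an iteration and recomputed only when the dose-response
  parameters change; the $\lambda$-block updates maintain the mixture
  normalization incrementally under a per-iteration anchor, so an
  iteration costs $O(m)$ rather than $O(m \cdot \mathrm{blocks})$.
* **Frequentist model averaging (FMA)** fits all $m$ vectors
  (`fma_fit_all()`), converts each profile interval to an SD as the
  minimum half-width divided by 1.96, draws $k = 100$ normal samples per
  fit, weights each sample by the AIC softmax
  $e^{-\mathrm{AIC}_j/2}/\sum_k e^{-\mathrm{AIC}_k/2}$
  (`fma_weights()`; lower AIC means higher weight) and reports the
  weighted mean with weighted 2.5/97.5% centiles (`fma_combine()`). A
  vector with one unbounded interval side reuses the finite side's
  half-width and is flagged; a vector with no finite side is excluded and
  counted. The asymmetric-interval variant (separate SDs above and below
  the estimate) is deliberately not implemented: it is known to be badly
  biased by occasional huge one-sided intervals.

## The study runner

`run_study()` crosses scenarios (by default the six Berkson combinations
of 0/20/50% shared and unshared, all with 20%/20% classical error) with
the two risk models, builds `n_meta` ensembles per cell, runs the
requested estimators and aggregates: coverage of the true coefficients,
mean coefficients, percent bias of the predicted ERR at 0.1 and 1 Gy
($100[(\alpha_m d + \beta_m d^2)/(\alpha d + \beta d^2) - 1]$,
`err_bias()`), dose correlations and convergence counts. Ensembles are
seeded by (master seed, risk form, ensemble index) — deliberately *not*
by scenario — so scenarios differing only in classical error share their
Berkson draws exactly and the classical-invariance of all true-dose
estimators holds bit-for-bit. Results are written as CSV tables
(`write_tables()`), and configurations round-trip through a plain-text
steering dialect (`read_steering()`/`write_steering()`) whose error
magnitudes accept `50%` or `0.5`.

Per-run BMA mixing diagnostics flag a fit unconverged when any BGR
exceeds 1.03 or a coefficient acceptance rate leaves 5–80%; the study
protocol summarizes these as the mean BGR over runs in the convergence
table rather than excluding runs, mirroring how such studies report
sampler quality. MLE-based fits that genuinely fail to converge *are*
excluded and counted.

## Problem sizes, tolerances and determinism

The full design (500 meta-ensembles × 1000 sub-simulations × 6 scenarios
× 2 risk models × 6 methods) is a large overnight computation. The
package's own verification runs at deliberately chosen smaller sizes: the
zero-error and unadjusted coverage checks use the full 500 ensembles
(cheap because degenerate error components are skipped), the
model-averaging scenario is scaled to 100 ensembles, and unit tests use a
trimmed 90-individual cohort. Every stochastic function takes an explicit
seed and restores the caller's RNG state; two calls with equal seeds are
bit-identical. Optimizer tolerances (gradient/decrement $10^{-8}$ scale,
profile-endpoint deviance within $10^{-3}$ of 3.841) are asserted by
oracle tests against brute-force grid scans and hand-summed likelihoods.

## What the generator does and does not emulate — known limitations

The generator reproduces the published study's error structure (shared
and unshared, Berkson and classical, lognormal, mean-preserving), its
grouped cohort shape and its case-sampling model. It does not emulate
covariates, stratification, time-dependent rates, non-lognormal error
families or continuous (ungrouped) doses, so passing tests say nothing
about those features of real data.

One behavioural caveat deserves emphasis. With this package's default
cohort the within-group averages wash out unshared Berkson noise, so the
$m$ dose vectors of an ensemble are very nearly a common-factor (scale)
family; all per-vector fits then achieve near-identical likelihoods (the
test suite asserts an AIC range below 1 across the vectors of a headline
ensemble), and the Bayesian-model-averaging mixture posterior is
genuinely broad. A collapse of BMA coverage to a few percent under large
shared Berkson error — the behaviour expected when the posterior seizes
on single, well-fitting but biased dose vectors — therefore does not
emerge here: under a scale family no vector is distinguishably better,
and a mixing sampler spreads its mass across them. This cell is
sensitive to cohort composition and to sampler mixing in ways the other
reported quantities are not; the acceptance script reports the honest
measured coverage together with the mean Brooks-Gelman-Rubin statistic.
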
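---
title: "Methods: sequential stabilized IPTW for a downstream trial phase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential stabilized IPTW for a downstream trial phase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqiptw)
```

## The estimation problem

A multiphase protocol — induction, up to two autologous stem cell
transplants (ASCT), then a consolidation phase — loses its randomization
balance whenever compliance with the intermediate phases depends on
prognosis. The package estimates the causal effect of the *final* phase on
progression-free survival (PFS, measured from the last transplant
evaluation) by re-weighting ASCT starters so that, in the weighted
pseudo-population, starting consolidation is independent of the measured
baseline covariates and of induction response.

Two sequential selection processes are modelled with logistic propensity
scores: PS1, the probability of starting at least one transplant, fitted on
all complete-case patients from the dichotomized baseline covariates and
treatment arm; and PS2, the probability of starting consolidation, fitted
*on ASCT starters only* (consolidation is only at risk of occurring there)
with the same covariates plus complete response at induction. Each score
yields a stabilized weight

$$\mathrm{SIPTW} = Z\,\frac{\pi}{p(\mathbf X)} + (1-Z)\,\frac{1-\pi}{1-p(\mathbf X)},$$

where $\pi$ is the observed marginal starting proportion within the phase's
at-risk set — the sample-count form (e.g. 362/414 for phase 1), not a
model-based marginal, because that is how the stabilization is defined from
trial-flow counts. The total weight is the product of the two stabilized
weights for starters and the phase-1 weight alone for non-starters, whose
second-phase weight does not exist. Stabilized weights have expectation 1
under a correctly specified score, so the pseudo-population keeps the
original sample size; this is asserted as a test invariant (sum of weights
within 2% of *n* at *n* = 5000).

Identification assumes no unmeasured confounding of either selection step,
positivity, and correct specification of both logistic models. None of these
are testable from the data; the balance table
(`standardized_differences()`) is the available diagnostic.

## Weighted survival estimation

**Kaplan–Meier.** The product-limit estimator uses weighted risk and event
sums. For the pointwise variance no standard form exists for arbitrary
weights, so the package uses a weighted Greenwood formula with *squared*
weights in the numerator,
$\widehat{\mathrm{Var}}\,\log S(t) = \sum_{t_j \le t} Y^{(2)}_j D_j / \{Y_j^3 (1 - D_j/Y_j)\}$
with $Y^{(2)}_j$ the squared-weight at-risk sum; at unit weights this is
exactly Greenwood's formula, which is also enforced by test.

**Log-rank.** Treating inverse-probability weights as frequency counts
understates the variance of the weighted log-rank statistic. The package's
variance therefore carries squared weights,
$V_j=\lambda_j(1-\lambda_j)\sum_{i\in R_j} w_i^2\,(g_i-\bar g_j)^2 \cdot \tilde n_j/(\tilde n_j-1)$,
where $\tilde n_j = Y_j^2 / Y_j^{(2)}$ is the effective (Kish) risk-set size
supplying the small-sample/ties correction. Two properties pinned this
choice: at unit weights it reduces *exactly* (including the ties factor) to
the classical log-rank variance, and it is invariant to rescaling all
weights by a constant. A purely robust score-based variance satisfies the
second property but not the first; a frequency-count variance satisfies
neither the robustness requirement nor nominal size. The implemented form
holds its size under informative weights (type-I error within [0.03, 0.07]
at $\alpha = 0.05$ over 1000 null replicates in the test suite).

**Aalen additive hazards.** At each ordered event time the increment vector
solves the weighted least-squares problem on the at-risk set,
$d\widehat B(t) = (X'WX)^{-1}X'W\,dN(t)$, with the covariate weights entering
as case weights (the cited weighted variants of the estimator give no single
canonical scaling; ordinary least squares per risk set with IPT case weights
is the implemented default). Variances accumulate the optional-variation
form $A\,\mathrm{diag}(dN)\,A'$ with $A=(X'WX)^{-1}X'W$. Tied event times
are aggregated into a single increment. Estimation stops at the first event
time whose at-risk normal-equations matrix is singular (reciprocal condition
number below 1e-10) — standard additive-hazards practice, since late risk
sets are small — and later increments are left undefined rather than
regularized. Two exact identities anchor the implementation: the
intercept-only cumulative baseline equals the weighted Nelson–Aalen
estimator, and unit-weight increments match an independent reference
implementation.

`suggest_changepoint()` operationalizes the visual reading of the
cumulative-coefficient plot: a continuous two-segment linear fit over a
candidate grid of event times, minimizing residual sum of squares, with a
"no change" flag when the segment slopes agree within 1e-6. It is advisory
only; the Cox stage takes its changepoint as explicit input (default 18
months), because an automatically estimated changepoint would invalidate the
downstream inference.

**Weighted Cox with episode splitting.** Follow-up of consolidated patients
is split at the changepoint into an early episode (0, c] with an `early`
dummy and a late episode (c, T] with a `late` dummy; both dummies are zero
for non-consolidated patients, and an episode ending exactly at the
changepoint belongs to the early interval. Events are conserved by the
split. The weighted partial likelihood uses Breslow tie handling (the
simple closed weighted form; simulated continuous times make ties rare) and
counting-process risk sets, maximized by Newton–Raphson with step halving,
convergence at relative log-likelihood change below 1e-8, at most 50
iterations, and monotone-likelihood detection at |log HR| > 15. The robust
variance is the Lin–Wei sandwich $A^{-1}BA^{-1}$ with per-*patient*
aggregation of score residuals before the outer product: clustering on
patient is the defensible default when one subject contributes several
episodes. The sandwich is invariant to rescaling all weights — asserted
analytically in the tests (estimates and robust SEs unchanged, naive SEs
shrink) — and matches the reference weighted implementation to 1e-6.

**Proportional-hazards diagnostic.** The Schoenfeld test regresses weighted
scaled Schoenfeld residuals on event time (identity transform; no transform
is canonical here and the identity keeps the early/late split
interpretable), giving score-type chi-squares per term and globally.
Weights are normalized to mean 1 inside the test so that it, too, is
invariant to weight rescaling. The test's operating characteristics are
established by simulation in the suite: size within [0.03, 0.08] under a
constant hazard ratio, power above 0.8 against crossing hazards, and — the
workflow's signature behaviour — rejection before episode splitting followed
by non-rejection after splitting at the true changepoint.

## The synthetic-trial generator

`sim_config()` defaults define the study conditions: 414 patients (the
complete-case size of the motivating trial), 1:1 arm allocation, age normal
(mean 56, SD 7.21 years) truncated to the 18–65-year eligibility window,
and the published baseline prevalences for the ten binary/categorical
factors (e.g. male 57.00%, del(13q) 48.31%, ISS distribution
43.48/39.13/17.39%). The true selection processes use the published
propensity-model point estimates for both phases, so simulated selection
strength matches the study. Outcomes follow a piecewise-exponential PFS
model sampled by inverse-CDF (seed-exact): consolidation multiplies the
baseline hazard by 0.40 before the 18-month changepoint and by 1.98 after
it — the weighted early/late estimates of the motivating analysis — making
parameter recovery a meaningful end-to-end check.

Two generator constants are not reported anywhere and were fixed once at
field-realistic values: the baseline hazard, 0.024 events/month, chosen so
that one-year PFS of non-consolidated starters is about 75%, matching the
order of the reported weighted one-year survival; and the
complete-response-at-induction probability, 0.30, a typical
post-bortezomib-induction CR rate in newly diagnosed myeloma. Censoring is
purely administrative at 54 months (the reported median follow-up); the
motivating paper does not describe its censoring process, so no random
censoring is imposed by default (a rate parameter exists).

What the generator deliberately does **not** emulate: covariate correlation
(covariates are drawn independently at the published marginals — the joint
distribution is unpublished; a correlation structure would be configurable
future work); separate dropout causes (toxicity vs progression) behind the
selection probabilities; the unexplained gap between patients who started
ASCT and those evaluated for PFS in the source trial (the simulator analyses
all starters and is self-consistent); and any direct effect of induction
response on the hazard. Passing tests therefore demonstrate correctness of
the estimation machinery under the stated data-generating mechanism, not
robustness to correlated covariates, unmeasured confounding, or informative
censoring.

## Numerical choices and degenerate inputs

* Propensity fitting delegates to IRLS (epsilon 1e-8, max 25 iterations);
  separation (non-convergence, non-finite information, |coefficient| > 15)
  is an error advising covariate removal, as is a rank-deficient design or
  an outcome with no variation. Confidence intervals are Wald
  (estimate ± 1.959964 SE), matching the symmetric intervals of published
  selection-model tables.
* Fitted probabilities are clamped to [1e-6, 1 − 1e-6] at prediction and
  the clamp count is reported: a fitted score of exactly 1 would give an
  untreated patient an infinite weight. A propensity score of 0 or 1
  *supplied* to the weight functions is an error, never silently clipped.
* No weight truncation by default; `compute_weights()` has an optional
  truncation quantile. Weights above 2 are counted and flagged rather than
  altered.
* Ties: survival times tied at an event time are aggregated, with events
  ranked before censorings at the same time.
* All Monte-Carlo behaviour is seed-deterministic; the generator's
  inverse-CDF sampling makes event times exact functions of the uniform
  stream.

## Problem sizes used in validation

The suite exercises closed-form fixtures (n ≤ 30) against brute-force
oracles and reference implementations; distributional recovery at
n = 50,000; stabilization and balance at n = 5,000; log-rank size over
1,000 null replicates (n = 150 each); Schoenfeld size over 500 replicates;
changepoint recovery over 200 replicates at n = 1,000; and full
parameter-recovery and diagnostic studies over 200 replicates at the study
size n = 414. These sizes keep each property's Monte-Carlo error small
relative to its assertion band.

## Known limitations

* Both selection events are one-time: no time-updated (marginal structural
  model) weighting for longitudinal exposures.
* The Cox stage models the treatment effect with exactly two intervals;
  smoother time-varying coefficients are out of scope, as are frailty terms
  and competing risks.
* Confidence bands for the Aalen cumulative coefficients are pointwise, not
  simultaneous; no formal supremum test of time-invariance is provided.
* The final weighted Cox model contains the consolidation dummies only
  (confounding is handled entirely by the weights); additional covariate
  columns in the episode table can be included via `terms` if doubly robust
  adjustment is wanted.
* Patients who never started a transplant contribute to the phase-1
  propensity model and weights but are excluded from all outcome models:
  their time origin does not exist.
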
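# seqiptw

Sequential stabilized inverse-probability-of-treatment weighting (IPTW) for
estimating the causal effect of a **single downstream phase** of a multiphase
randomized trial when compliance erodes the randomization balance.

## The problem

In complex oncology protocols — induction therapy, then autologous stem cell
transplantation (ASCT), then a consolidation phase — patients drop out between
phases for reasons tied to prognosis. An intention-to-treat contrast dilutes
the phase-specific effect; a per-protocol contrast compares groups that are no
longer exchangeable. `seqiptw` implements the standard causal repair: model
each selection step with a propensity score, weight patients by stabilized
inverse probabilities, and analyse survival in the weighted pseudo-population,
mimicking a trial that randomized the consolidation phase itself.

For patient *i* with covariates **X** and phase indicator *Z*, the propensity
score is p(**X**) = Pr(Z = 1 | **X**), the weight is
w = Z/p(**X**) + (1 − Z)/(1 − p(**X**)), and the stabilized weight multiplies
w by the marginal probability of the phase actually received. With two
sequential phases (transplant, then consolidation among the transplanted) the
total stabilized weight is the product of the per-phase stabilized weights;
for patients who never reached the second phase it is the first-phase weight
alone. Outcomes are analysed with:

* weighted Kaplan–Meier curves and a weighted log-rank test (squared-weight
  variance),
* a weighted Aalen additive hazards model, whose cumulative regression
  coefficients B_k(t) localize *when* the treatment acts,
* a weighted Cox model with follow-up split at a changepoint (default 18
  months) into early/late treatment dummies and Lin–Wei robust sandwich
  variance clustered on patient.

Because patient-level trial data of this kind are not public, the package
ships a synthetic multiphase-trial generator (`simulate_trial()`) with
realistic covariate prevalences, published selection-model coefficients as the
true selection process, and a piecewise-constant consolidation effect on the
hazard, so every stage is testable end to end.

## Worked example

```r
library(seqiptw)
cohort <- simulate_trial(sim_config(n_patients = 414, seed = 2026))
fit <- run_pipeline(cohort)
print(fit)
```

```
Sequential stabilized-IPTW analysis of the consolidation phase
  414 patients; 318 (76.81%) started the first transplant; 237 (74.53%) of starters consolidated
  note: 4 total weights exceed 2 (inspect these patients)

Total stabilized weight: 1.00 +/- 0.33  range 0.52-4.79  (n = 414, 4 above 2)

Weighted log-rank test: chisq = 0.1753 on 1 df, p = 0.6754

Suggested changepoint: 21.9 months (segment slopes -0.01676 before, 0.02003 after)

Unsplit model PH test p (global): 1.325e-10

Episode-split weighted Cox model (changepoint 18 months):
Weighted Cox model: 251 events, 523 episodes, 318 patients (converged in 4 iterations)
  term   coef    HR robust SE HR low HR high        p
 early -1.310 0.269     0.277  0.156   0.462 2.11e-06
  late  0.594 1.810     0.268  1.070   3.060 2.70e-02
  split-model PH test p (global): 0.299
```

Reading the output: the stabilized weights average 1 and so preserve the
sample size; the log-rank test on the whole follow-up sees nothing (the
early benefit and late excess cancel); the Schoenfeld test on the single
consolidation dummy rejects proportional hazards decisively; after splitting
at 18 months the early hazard ratio (true generating value 0.40) and the late
hazard ratio (true 1.98) are both recovered within their robust confidence
intervals, and the split model satisfies proportional hazards. The Aalen
cumulative-coefficient trajectory suggests a changepoint near the true 18
months.

`write_report(fit, "out/")` serializes the full report (JSON plus per-stage
delimited tables); `inst/scripts/seqiptw-cli.R` exposes `simulate`,
`analyze`, `full` and `recover` subcommands over the same functions.

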
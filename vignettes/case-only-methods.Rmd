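---
title: "Case-only analysis of biomarker-treatment interactions: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-only analysis of biomarker-treatment interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caseonly)
```

## The problem

Early studies of predictive biomarkers ask whether the relative benefit of
an experimental treatment differs between patients with high and low levels
of a binary marker $M$. With a failure-time endpoint, the standard analysis
is a Cox regression on the whole cohort with a multiplicative
marker-treatment interaction. These studies are typically small (a few
hundred patients) and the interaction coefficient is notoriously
power-hungry, so small-sample bias and non-convergence are practical
concerns rather than asymptotic footnotes.

The *case-only* alternative uses only the $K$ patients who experience the
event. Under three assumptions — the event is rare over follow-up,
censoring is non-informative, and treatment assignment is independent of
marker level (guaranteed by randomization) — the logistic regression of
*treatment* on *marker* among cases estimates the same interaction
coefficient as the full-cohort Cox model, while requiring biomarker
measurements on cases only. This package implements that estimator with
Firth's bias-eliminating penalization, its full-cohort Firth-Cox
comparator, the cohort simulator needed to study both, and the
Monte-Carlo performance measures (bias, EmpSE/ModSE, coverage, power)
used to summarize replicated runs.

## Models

Cohort subjects carry $(M, T, \text{time}, \text{event})$ with $M, T \in
\{0, 1\}$. The full-cohort comparator is the Cox model

$$h(t \mid M, T) = h_0(t)\, \exp(\beta_M M + \beta_T T + \beta_I MT),$$

or, in the subgroup parametrization, $h_0(t) \exp(\beta_M M +
\beta_{TM_{low}} T(1-M) + \beta_{TM_{high}} TM)$, where
$\beta_I = \beta_{TM_{high}} - \beta_{TM_{low}}$ is the log interaction
hazard ratio.

For a case failing at $t_e$, let $p_e$ be the fraction of the cohort still
at risk at $t_e$ that is assigned to the experimental arm. The case-only
model is the offset logistic regression

$$\operatorname{logit} P(T = 1 \mid t_e, M) =
  \log \frac{p_e}{1 - p_e} + \gamma_T + \gamma_I M,$$

with the subgroup form replacing $\gamma_T + \gamma_I M$ by
$\gamma_{TM_{low}}(1 - M) + \gamma_{TM_{high}} M$. The offset absorbs the
(time-varying) treatment composition of the risk set; under the three
assumptions above $\gamma_I \approx \beta_I$ and the subgroup coefficients
approximate their Cox counterparts, so the $\gamma$'s are read as log
hazard ratios even though they come from a logistic fit. The offset uses
only treatment assignments and follow-up times — this is exactly why
non-cases need no marker measurement, and why the design saves
$100(1 - K/n)\%$ of assays.

### Firth penalization

Both fits maximize a Jeffreys-prior penalized likelihood
$\ell^*(\theta) = \ell(\theta) + \tfrac12 \log \det I(\theta)$, with
$I$ the (partial-likelihood) information. For the logistic model the
penalized score has the closed hat-diagonal form
$U^*(\gamma) = X^\top\!\big(y - \pi + h(\tfrac12 - \pi)\big)$; for the Cox
model the penalty gradient is evaluated by central finite differences of
$\tfrac12 \log\det I(\beta)$ (step $10^{-4}$), with the Newton direction
taken from the unpenalized information, the standard construction for
penalized partial likelihood. The penalization removes the leading
$O(n^{-1})$ bias of the estimates and — its best-known side effect —
keeps estimates finite under separation (logistic) and monotone
likelihood (Cox), both of which occur regularly when a 2-by-2 cell has
no events. The penalty deliberately shrinks *all* coefficients,
including the intercept-like $\gamma_T$; this is the standard correction
and leaves a small (percent-level) residual shrinkage even at large $n$.

### Confidence intervals and tests

Wald intervals use the inverse information at the optimum. Profile
penalized-likelihood (PL) bounds solve
$2\{\ell^*(\hat\theta) - \ell^*_{\text{profile}}(b)\} = \chi^2_{1,0.95}$,
found by expanding a bracket geometrically outward from the Wald bound
and polishing with Brent root-finding; each bound carries its own
convergence flag, and a bound is declared failed after 200 profile
evaluations. The PL test p-value is the penalized likelihood-ratio
p-value from the constrained fit at zero, so test and interval are dual
by construction. Both interval types are reported throughout because
their small-sample behaviour differs materially (PL power is
consistently a few points higher at these sample sizes).

## The cohort generator

Each subject lands in one of the four $(M, T)$ cells with probabilities
determined by the marker prevalence $p_M$, the treated fraction $p_T$ and
the marker-treatment odds ratio $\mathrm{OR}_{MT}$: the joint cell
$p_{11}$ solves the quadratic
$\mathrm{OR}_{MT}(p_M - p_{11})(p_T - p_{11}) =
p_{11}(1 - p_M - p_T + p_{11})$, which has exactly one root in the
Fréchet interval for any positive odds ratio. Assignment is i.i.d.
multinomial rather than exact quota: per-dataset cell-count variation is
part of small-sample behaviour, not noise to be suppressed.

Event times are drawn by inverse-CDF sampling from the exponential
proportional-hazards model
$t_e = -\log(U_e) / \{\lambda_e \exp(\beta_M M + \beta_T T +
\beta_I MT)\}$ with the baseline rate
$\lambda_e = -\log(1 - q_e)/t_{end}$ calibrated so a fraction $q_e$ of
reference-cell subjects fails by the horizon $t_{end}$. Censoring times
are exponential with rate calibrated to $q_c$ and all covariate effects
set to zero — censoring is non-differential by construction. A subject is
an event iff $t_e < \min(t_c, t_{end})$ (boundary ties, a measure-zero
set, are censored). A Weibull baseline (shape $k$, scale chosen to keep
the reference event fraction at $q_e$) is available for sensitivity work;
shapes 0.5 and 1.5 are the defaults for decreasing and increasing
hazards, our choice in the absence of an established convention, and
censoring stays exponential there so that non-differential censoring is
preserved.

Default scenario settings are the study conditions the package is built
around: $p_T = 0.5$, $q_e = q_c = 0.2$, $t_{end} = 5$ years,
$\mathrm{HR}_T = 1$, with grids over $n \in \{200, \ldots, 1000\}$,
$p_M \in \{0.25, 0.5, 0.75\}$, $\mathrm{HR}_M \in \{0.6, 0.8, 1, 3, 6\}$,
$\mathrm{OR}_{MT} \in \{0.5, 1, 2\}$ and
$\mathrm{HR}_I \in \{0.25, 0.5, 0.75, 1\}$; these mirror the breast-cancer
biomarker studies that motivate the scenario space (samples of a few
hundred, markers from protective to strongly harmful, near-balanced
randomization).

What the generator does *not* emulate: covariate-dependent or informative
censoring, time-varying treatment effects or hazards beyond the Weibull
family, more than two marker levels, and measurement error in $M$.
Passing tests therefore speak to the estimators' behaviour under the
stated sampling model, not to robustness against those violations.

## Case-only dataset construction

Risk-set membership uses follow-up time $\ge t$, so a case belongs to its
own risk set — the convention that matches the partial-likelihood analogy.
Tied event times share the risk set evaluated at the common time. A case
whose risk set is single-armed ($p_e \in \{0, 1\}$) has an infinite
offset that carries no information for the logistic fit; such cases are
dropped, counted, and reported per scenario. These conventions are our
own design decisions where the construction leaves room.

## Performance measures and filters

Per scenario, method and coefficient we report bias (and relative bias
as a percentage when the true value is nonzero — for null-interaction
scenarios relative bias is undefined and the rejection rate is labelled
type-I error), empirical SE with the $N_c - 1$ denominator, model SE as
the root mean model variance, the relative ModSE error
$100(\widehat{\mathrm{ModSE}}/\widehat{\mathrm{EmpSE}} - 1)$, coverage
and power for both interval types, and convergence counts. Replicates
enter only if (i) events occurred in at least three of the four cells
and (ii) the fit converged, meaning the solver met its score tolerance
in fewer than the maximum iterations. PL coverage and power are computed
over the further subset where both profile bounds converged, because
interval membership is undecidable otherwise; the Wald denominator stays
$N_c$. Truth for the case-only coefficients is the generating Cox-scale
value, since the design's purpose is to estimate precisely those.

## Numerical choices

* Logistic solver: Fisher scoring with the modified score, step-halving
  on penalized-likelihood decrease, score tolerance $10^{-8}$, iteration
  cap 1000 (the cap mirrors the Cox setting; the logistic fits converge
  in around ten iterations).
* Cox solver: Newton steps rescaled so no element exceeds
  `max_step = 0.01` with an iteration cap of 1000 — deliberately
  conservative solver settings chosen to make convergence failures
  informative rather than erratic; profile and constrained fits reuse
  the same settings, warm-started from the unconstrained optimum.
  Ties use the Breslow approximation: simulated times are continuous,
  so ties have probability zero and the cheapest convention suffices.
* The Cox likelihood machinery collapses subjects to unique covariate
  patterns (at most four here), reducing every score/information
  evaluation to a small matrix product of an events-by-patterns
  risk-count matrix; this is what makes $10^3$–$10^4$ replicate fits
  per scenario practical in plain R.
* Degenerate information matrices fall back to a pseudo-inverse during
  iteration; final variance matrices are reported as `NA` if singular at
  the optimum.
* Seeding: replicate $j$ of a scenario uses a fixed integer mix of the
  master seed and $j$ (kept below $2^{31}$), so single replicates are
  reproducible in isolation; grid scenarios key their seed on their own
  settings, so results are invariant to grid order or subsetting.

## Problem sizes in the shipped checks

The package's acceptance checks rerun single scenarios at desk scale:
2000–3000 replicates for case-only rows, 1000–1500 for the
slower-to-solve full-cohort Firth-Cox rows, and they compare Monte-Carlo
percentages within three combined binomial standard errors of the
reference values (at 2000 replicates, a 95% coverage has MC SE of about
0.5 points). Structural properties — penalized optima against
brute-force grid maximization on six-subject fixtures, the
reparametrization identity
$\hat\beta_I = \hat\beta_{TM_{high}} - \hat\beta_{TM_{low}}$,
the $(y + \tfrac12)/(n + 1)$ closed form, PL/Wald agreement at
$n = 10^5$, and recovery plus directional breakdown of the case-only
approximation — hold at much tighter tolerances and do not depend on
replicate counts.

## Known limitations

The case-only estimator is *not* robust: with a harmful marker
($\mathrm{HR}_M > 1$, hence a high event rate) it is biased towards the
null irrespective of sample size, and with marker-treatment dependence
($\mathrm{OR}_{MT} \ne 1$) it is severely biased with inflated type-I
error — the package reproduces both failure modes and they are asserted
as such in the test suite. Recoding a harmful marker as protective does
not rescue the design, because the event rate is unchanged. The marker
main effect is not estimable from cases only, and the Firth correction's
intercept shrinkage leaves a few percent of residual bias even at large
$n$. Users analyzing real cohorts should treat the rare-event and
independence assumptions as entry conditions, not fine print.

## A small worked run

```{r, eval = FALSE}
cfg <- scenario_config(n = 400, p_M = 0.25, hr_M = 0.8, hr_I = 0.5,
                       n_reps = 500, seed = 1)
res <- run_scenario(cfg, methods = c("caseonly_firth", "cox_firth"),
                    ci = "both")
res$summary
```
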
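# caseonly

Simulation framework and penalized estimators for **case-only analysis of
predictive biomarker–treatment interactions** in small survival studies.

## The problem

A predictive biomarker modifies the relative effect of a treatment; the
quantity of interest is the interaction hazard ratio
HR<sub>I</sub> = exp(β<sub>I</sub>) in the Cox model

```
h(t | M, T) = h0(t) · exp(β_M·M + β_T·T + β_I·M·T)
```

for a binary marker M and treatment T. Early biomarker studies are small
(a few hundred patients), so the full-cohort interaction estimate suffers
small-sample bias, monotone-likelihood failures and low power — and every
patient needs an expensive marker assay.

The *case-only* design analyzes only the K patients who experience the
event, fitting a logistic regression of treatment on marker with a fixed
per-case offset log(p<sub>e</sub>/(1−p<sub>e</sub>)), where p<sub>e</sub>
is the treated fraction of the full-cohort risk set at that case's event
time:

```
logit P(T = 1 | t_e, M) = log(p_e/(1−p_e)) + γ_T + γ_I·M
```

When the event is rare, censoring is non-informative and treatment is
independent of marker (e.g. randomized), γ<sub>I</sub> ≈ β<sub>I</sub>:
the interaction is estimable from cases alone, cutting biomarker
measurements by 80% or more. Both fits are available with Firth's
Jeffreys-prior penalization (finite estimates under separation /
monotone likelihood, first-order bias removed) and with Wald and
profile-likelihood confidence intervals.

The package provides:

* `scenario_config()` / `generate_cohort()` — cohorts with a controlled
  marker–treatment odds ratio and exponential (or Weibull) event times;
* `build_case_only()` — case selection and risk-set offsets;
* `fit_logistic()` — offset logistic regression with/without Firth
  penalization, profile-likelihood CIs (`profile_ci()`) and penalized-LR
  tests (`lr_test()`);
* `fit_cox()` — the full-cohort Firth-penalized Cox comparator
  (iteration cap 1000, Newton step capped at 0.01);
* `summarize_performance()`, `run_scenario()`, `run_grid()` — the
  Monte-Carlo engine: bias, EmpSE/ModSE, coverage, power/type-I error
  with eligibility and convergence filters;
* a command-line front end in `inst/cli/caseonly_cli.R`
  (`simulate` / `fit` / `grid`).

## A worked example

Five hundred replicates of a 400-patient randomized scenario with a
protective marker (HR_M = 0.8, prevalence 0.25), no treatment effect at
low marker level and interaction HR_I = 0.5:

```r
library(caseonly)
cfg <- scenario_config(n = 400, p_M = 0.25, hr_M = 0.8, hr_I = 0.5,
                       n_reps = 500, seed = 1)
res <- run_scenario(cfg, methods = c("caseonly_firth", "cox_firth"),
                    ci = "both")
res$summary
#>           method coefficient  truth    bias rel_bias_pct emp_se mod_se
#> 1 caseonly_firth           I -0.693  0.0267         3.85  0.695  0.780
#> 2      cox_firth           I -0.693 -0.0211        -3.04  0.712  0.753
#>   rel_err_mod_se_pct coverage_wald_pct coverage_pl_pct power_wald_pct
#> 1              12.28              97.2            95.4            7.2
#> 2               5.77              97.0            96.6           11.2
#>   power_pl_pct measure n_c n_c_pl mean_events
#> 1         14.0   power 500    500          65
#> 2         16.8   power 500    500          65
```

Reading the row for the Firth case-only method: across converged,
eligible replicates the interaction estimate is nearly unbiased (relative
bias 3.9%), the model SE overstates the empirical SE by 12% at this
sample size, coverage of the 95% intervals is slightly above nominal
(97.2% Wald, 95.4% profile-likelihood), and power to detect HR_I = 0.5 is
low — 7% (Wald) to 14% (PL) — as expected at 400 patients with only ~65
events. The full-cohort Firth-Cox comparator behaves similarly here while
requiring marker assays on all 400 patients instead of ~65 cases
(an ~84% saving).

A single dataset can be analyzed directly:

```r
coh <- generate_cohort(cfg, seed = 1)            # or read_cohort("cohort.csv")
co  <- build_case_only(coh)
fit_logistic(cbind(gamma_T = 1, gamma_I = co$M), co$T,
             offset = co$offset, firth = TRUE)
#> Firth-penalized logistic regression with offset
#>            coef     se wald lo wald hi   pl lo  pl hi
#> gamma_T -0.2961 0.2665 -0.8184  0.2262 -0.8245 0.2170
#> gamma_I -0.0975 0.7727 -1.6119  1.4169 -1.6383 1.3221
#> loglik (penalized) = -42.8817, converged = TRUE (10 iterations)
```

See `vignettes/case-only-methods.Rmd` for the models, the generator's
design, the eligibility/convergence filters and all numerical choices.

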
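test_that("unpenalized Cox fit matches survival::coxph", {
  skip_if_not_installed("survival")
  for (seed in c(41, 42)) {
    coh <- fixture_cohort(n = 400, seed = seed, hr_M = 0.8, or_MT = 2)
    f <- fit_cox(coh, "interaction", firth = FALSE, pl = FALSE,
                 max_step = 0.5, tol = 1e-9)
    ref <- survival::coxph(survival::Surv(time, event) ~ M + T + M:T,
                           data = coh, ties = "breslow")
    expect_equal(unname(coef(f)), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(f$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
  }
})

test_that("penalized optimum matches grid maximization on a tiny fixture", {
  # six subjects, distinct times, all three design columns vary
  coh <- as_cohort(data.frame(
    M = c(0, 1, 0, 1, 1, 0), T = c(0, 1, 1, 0, 1, 0),
    time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 1, 1, 0, 1)))
  f <- fit_cox(coh, "interaction", firth = TRUE, pl = FALSE,
               max_step = 0.5, tol = 1e-9)
  X <- cbind(coh$M, coh$T, coh$M * coh$T)
  oracle <- grid_maximize(
    function(b) penll_cox_direct(b, X, coh$time, coh$event, firth = TRUE),
    p = 3)
  expect_equal(unname(coef(f)), unname(oracle), tolerance = 1e-4)
  expect_equal(f$loglik,
               penll_cox_direct(coef(f), X, coh$time, coh$event),
               tolerance = 1e-8)
})

test_that("Firth penalization yields finite estimates under monotone likelihood", {
  # no events among treated high-marker subjects: the ML estimate of the
  # interaction diverges, the penalized one stays finite
  coh <- fixture_cohort(n = 300, seed = 43, hr_M = 0.8)
  coh$event[coh$M == 1 & coh$T == 1] <- 0L
  # the three remaining cells still have events
  expect_true(eligibility(coh))
  f <- fit_cox(coh, "interaction", firth = TRUE, pl = FALSE)
  expect_true(f$converged)
  expect_true(all(is.finite(coef(f))))
  expect_lt(max(abs(coef(f))), 10)
  f_ml <- fit_cox(coh, "interaction", firth = FALSE, pl = FALSE,
                  max_step = 0.5, max_iter = 200)
  # the ML interaction estimate drifts towards -Inf (the score only
  # vanishes in the limit); either the solver gives up or the estimate
  # has left any plausible range
  expect_true(!f_ml$converged || abs(coef(f_ml)[["MT"]]) > 5)
})

test_that("Cox parametrizations are one reparametrization", {
  for (seed in c(44, 45)) {
    coh <- fixture_cohort(n = 300, seed = seed, hr_M = 3, or_MT = 0.5)
    f1 <- fit_cox(coh, "interaction", firth = TRUE, pl = FALSE,
                  max_step = 0.5)
    f2 <- fit_cox(coh, "subgroup", firth = TRUE, pl = FALSE,
                  max_step = 0.5)
    expect_equal(coef(f1)[["MT"]],
                 coef(f2)[["TM_high"]] - coef(f2)[["TM_low"]],
                 tolerance = 1e-5)
    expect_equal(f1$loglik, f2$loglik, tolerance = 1e-7)
  }
})

test_that("large-cohort interaction estimate recovers the generating value", {
  cfg <- scenario_config(n = 2e4, hr_M = 1, hr_T = 1, hr_I = 0.5,
                         or_MT = 1)
  coh <- generate_cohort(cfg, seed = 46)
  f <- fit_cox(coh, "interaction", firth = TRUE, pl = FALSE,
               max_step = 0.5)
  expect_lt(abs(coef(f)[["MT"]] - log(0.5)), 3 * f$se[["MT"]])
})

test_that("profile bounds match a grid scan of the profile partial deviance", {
  coh <- as_cohort(data.frame(
    M = c(0, 1, 0, 1, 1, 0), T = c(0, 1, 1, 0, 1, 0),
    time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 1, 1, 0, 1)))
  f <- fit_cox(coh, "interaction", firth = TRUE, max_step = 0.5,
               tol = 1e-9)
  X <- cbind(coh$M, coh$T, coh$M * coh$T)
  prof <- function(b) {
    # independent 2-D maximization over the nuisance coefficients
    o <- optim(c(0, 0), function(nu)
      -penll_cox_direct(c(nu[1], nu[2], b), X, coh$time, coh$event),
      method = "Nelder-Mead",
      control = list(reltol = 1e-12, maxit = 5000))
    -o$value
  }
  dev <- function(b) 2 * (f$loglik - prof(b)) - qchisq(0.95, 1)
  lo <- uniroot(dev, c(coef(f)[["MT"]] - 8, coef(f)[["MT"]]),
                tol = 1e-7)$root
  hi <- uniroot(dev, c(coef(f)[["MT"]], coef(f)[["MT"]] + 8),
                tol = 1e-7)$root
  expect_equal(unname(f$pl_ci["MT", c("lower", "upper")]), c(lo, hi),
               tolerance = 1e-3)
  expect_lt(f$pl_ci["MT", "lower"], coef(f)[["MT"]])
  expect_gt(f$pl_ci["MT", "upper"], coef(f)[["MT"]])
})

test_that("profile and Wald intervals agree on large samples", {
  cfg <- scenario_config(n = 3e4, hr_M = 0.8, hr_I = 0.5)
  coh <- generate_cohort(cfg, seed = 47)
  f <- fit_cox(coh, "interaction", firth = TRUE, max_step = 0.5)
  wald_half <- diff(f$wald_ci["MT", ]) / 2
  pl_half <- diff(f$pl_ci["MT", c("lower", "upper")]) / 2
  expect_lt(abs(pl_half - wald_half) / wald_half, 0.02)
})

test_that("zero-event and collinear inputs are rejected", {
  coh <- as_cohort(data.frame(M = 0:1, T = 0:1, time = c(1, 2),
                              event = c(0, 0)))
  expect_error(fit_cox(coh), "no events")
  coh2 <- as_cohort(data.frame(M = c(0, 1, 0, 1), T = c(0, 1, 0, 1),
                               time = 1:4, event = c(1, 1, 1, 0)))
  expect_error(fit_cox(coh2, "interaction"), "collinear")
})

test_that("bias behaviour is insensitive to the censoring rate", {
  # the full-cohort estimator's bias should be qualitatively unchanged
  # when the non-administrative censoring fraction doubles
  bias <- vapply(c(0.1, 0.2), function(qc) {
    cfg <- scenario_config(n = 400, hr_M = 3, hr_I = 0.5, q_c = qc,
                           n_reps = 150, seed = 48)
    s <- run_scenario(cfg, methods = "cox_firth", ci = "wald")$summary
    s$bias
  }, 0)
  expect_lt(abs(bias[1] - bias[2]), 0.15)
})
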
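test_that("cell probabilities honour margins and odds ratio", {
  # independence factorizes
  expect_equal(cell_probabilities(0.25, 0.5, 1),
               c(p00 = 0.375, p01 = 0.375, p10 = 0.125, p11 = 0.125))
  expect_equal(unname(cell_probabilities(0.5, 0.5, 1)), rep(0.25, 4))

  # 1-D root-finding oracle for the dependent case, plus a brute grid
  or_constraint <- function(p11, p_M, p_T, or) {
    or * (p_M - p11) * (p_T - p11) - p11 * (1 - p_M - p_T + p11)
  }
  p11_oracle <- uniroot(or_constraint, c(1e-9, 0.25 - 1e-9),
                        p_M = 0.25, p_T = 0.5, or = 2, tol = 1e-12)$root
  grid <- seq(1e-6, 0.25 - 1e-6, length.out = 200001)
  p11_grid <- grid[which.min(abs(or_constraint(grid, 0.25, 0.5, 2)))]
  expect_equal(p11_oracle, p11_grid, tolerance = 1e-5)
  expect_equal(unname(cell_probabilities(0.25, 0.5, 2)["p11"]), p11_oracle,
               tolerance = 1e-9)

  # post-conditions over a sweep of margins and odds ratios
  for (p_M in c(0.1, 0.25, 0.75)) for (p_T in c(0.3, 0.5)) {
    for (or in c(0.2, 0.5, 1, 2, 7)) {
      p <- cell_probabilities(p_M, p_T, or)
      expect_equal(sum(p), 1)
      expect_true(all(p > 0))
      expect_equal(unname(p["p10"] + p["p11"]), p_M)
      expect_equal(unname(p["p01"] + p["p11"]), p_T)
      expect_equal(unname(p["p11"] * p["p00"] / (p["p10"] * p["p01"])), or)
    }
  }
  expect_error(cell_probabilities(0, 0.5, 1))
})

test_that("rate parameter matches the cumulative event fraction", {
  expect_equal(rate_parameter(0.2, 5), -log(0.8) / 5)
  expect_equal(rate_parameter(0.2, 5), 0.044629, tolerance = 1e-5)
  expect_identical(rate_parameter(0, 5), 0)
  for (q in c(0.01, 0.2, 0.9)) for (t_end in c(1, 5, 20)) {
    expect_equal(exp(-rate_parameter(q, t_end) * t_end), 1 - q)
  }
  expect_error(rate_parameter(1, 5))
  expect_error(rate_parameter(-0.1, 5))
})

test_that("cohort generator reproduces its design quantities", {
  n <- 1e5
  cfg <- scenario_config(n = n, p_M = 0.25, p_T = 0.5, or_MT = 1,
                         hr_M = 1, hr_T = 1, hr_I = 1, q_e = 0.2,
                         q_c = 0, n_reps = 1)
  coh <- generate_cohort(cfg, seed = 71)

  # event fraction forced by the rate construction (all cells identical)
  mc3 <- 3 * sqrt(0.2 * 0.8 / n)
  expect_lt(abs(mean(coh$event) - 0.2), mc3)

  # empirical marker-treatment odds ratio ~ 1 under independence
  tab <- table(coh$M, coh$T)
  or_hat <- tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
  expect_lt(abs(log(or_hat)), 3 * sqrt(sum(1 / tab)))

  # cell assignment: chi-square goodness of fit not rejected at 0.001
  counts <- as.vector(table(factor(2 * coh$M + coh$T, levels = 0:3)))
  gof <- chisq.test(counts, p = unname(cfg$cell_probs))
  expect_gt(gof$p.value, 0.001)

  # reference-cell event times are exponential with rate lambda_e
  ref <- coh$time[coh$M == 0 & coh$T == 0 & coh$event == 1]
  lam <- rate_parameter(0.2, 5)
  ks <- ks.test(ref, function(t) pexp(t, lam) / pexp(5, lam))
  expect_gt(ks$p.value, 0.001)
})

test_that("hazard ratios scale per-cell event fractions", {
  n <- 1e5
  for (hr_M in c(0.6, 3)) {
    cfg <- scenario_config(n = n, hr_M = hr_M, hr_T = 1, hr_I = 1,
                           q_e = 0.2, q_c = 0, n_reps = 1)
    coh <- generate_cohort(cfg, seed = 72)
    cell <- coh[coh$M == 1 & coh$T == 0, ]
    expected <- 1 - (1 - 0.2)^hr_M
    mc3 <- 3 * sqrt(expected * (1 - expected) / nrow(cell))
    expect_lt(abs(mean(cell$event) - expected), mc3)
  }
})

test_that("censoring is non-differential across cells", {
  # with a near-zero event rate almost every subject carries a censoring
  # time; its distribution must not depend on (M, T)
  cfg <- scenario_config(n = 4e4, hr_M = 3, hr_I = 0.5, q_e = 0.001,
                         q_c = 0.5, n_reps = 1)
  coh <- generate_cohort(cfg, seed = 73)
  cens <- coh[coh$event == 0 & coh$time < 5, ]
  ks <- ks.test(cens$time[cens$M == 1], cens$time[cens$M == 0])
  expect_gt(ks$p.value, 0.001)
  ks2 <- ks.test(cens$time[cens$T == 1], cens$time[cens$T == 0])
  expect_gt(ks2$p.value, 0.001)
})

test_that("mean observed event count matches the harmful-marker design", {
  # scenario with a strongly harmful marker at n = 600: the generator's
  # construction implies about 165 events per dataset on average
  cfg <- scenario_config(n = 600, p_M = 0.25, hr_M = 6, hr_T = 1,
                         hr_I = 0.5, q_e = 0.2, q_c = 0.2, n_reps = 300,
                         seed = 9)
  events <- vapply(seq_len(cfg$n_reps), function(j)
    sum(generate_cohort(cfg, seed = caseonly:::replicate_seed(9, j))$event),
    0)
  mc3 <- 3 * sd(events) / sqrt(length(events))
  expect_lt(abs(mean(events) - 165), mc3 + 1)  # +1 for table rounding
})

test_that("weibull baseline hits the reference event fraction", {
  for (shape in c(0.5, 1.5)) {
    cfg <- scenario_config(n = 5e4, hr_M = 1, hr_T = 1, hr_I = 1,
                           q_e = 0.2, q_c = 0, baseline = "weibull",
                           shape = shape, n_reps = 1)
    coh <- generate_cohort(cfg, seed = 74)
    mc3 <- 3 * sqrt(0.2 * 0.8 / nrow(coh))
    expect_lt(abs(mean(coh$event) - 0.2), mc3)
    # event times follow the intended Weibull law in the reference cell
    b <- 5 / (-log(0.8))^(1 / shape)
    ev <- coh$time[coh$event == 1]
    ks <- ks.test(ev, function(t) pweibull(t, shape, b) / pweibull(5, shape, b))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("configuration validation rejects impossible settings", {
  expect_error(scenario_config(n = 3), "n")
  expect_error(scenario_config(p_M = 1.2))
  expect_error(scenario_config(q_c = 1))
  expect_error(scenario_config(or_MT = -1))
  expect_error(scenario_config(hr_I = 0))
  expect_error(scenario_config(t_end = 0))
  expect_error(scenario_config(baseline = "weibull", shape = -2))
})

test_that("cohort CSV round-trips", {
  coh <- fixture_cohort(n = 50, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_s3_class(back, "cohort_data")
  expect_equal(as.data.frame(back), as.data.frame(coh), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(as_cohort(data.frame(M = 1, T = 1, time = -1, event = 1)))
  expect_error(as_cohort(data.frame(M = 2, T = 1, time = 1, event = 1)))
})
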
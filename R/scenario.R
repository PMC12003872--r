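#' Scenario configuration for cohort simulation
#'
#' Bundles every generator parameter for one simulation scenario: cohort
#' size, marker prevalence, treatment fraction, the marker-treatment odds
#' ratio, the three hazard ratios of the event model, event and censoring
#' fractions over the follow-up horizon, the baseline survival family, the
#' number of replicate datasets and the master seed.
#'
#' The event model is a proportional-hazards model on the four
#' marker-by-treatment cells: subjects in cell (M, T) have hazard
#' `lambda_e * exp(log(hr_M) * M + log(hr_T) * T + log(hr_I) * M * T)`,
#' with `lambda_e` chosen so that a fraction `q_e` of reference-cell
#' subjects (M = 0, T = 0) experience the event by `t_end` in the absence
#' of censoring. `hr_I` is the interaction hazard ratio: the ratio of the
#' treatment hazard ratios between high and low marker level.
#'
#' @param n cohort size (at least 4).
#' @param p_M prevalence of the high marker level, in (0, 1).
#' @param p_T fraction assigned to the experimental treatment, in (0, 1).
#' @param or_MT odds ratio of the marker-treatment association; 1 means
#'   assignment independent of marker (e.g. a randomized study).
#' @param hr_M hazard ratio of high vs. low marker under standard treatment.
#' @param hr_T hazard ratio of experimental vs. standard treatment at low
#'   marker level.
#' @param hr_I interaction hazard ratio.
#' @param q_e event fraction in the reference cell by `t_end`, pre-censoring.
#' @param q_c non-administrative censoring fraction by `t_end`; 0 disables
#'   random censoring (administrative censoring at `t_end` always applies).
#' @param t_end administrative follow-up horizon in years.
#' @param baseline `"exponential"` or `"weibull"`.
#' @param shape Weibull shape parameter (> 1 increasing hazard, < 1
#'   decreasing); ignored for the exponential baseline.
#' @param n_reps number of replicate datasets for scenario runs.
#' @param seed master seed; replicate `j` derives its own substream.
#' @return An object of class `scenario_config` (a named list).
#' @examples
#' cfg <- scenario_config(n = 600, hr_M = 0.6)
#' cfg$cell_probs
#' @export
scenario_config <- function(n = 600, p_M = 0.25, p_T = 0.5, or_MT = 1,
                            hr_M = 1, hr_T = 1, hr_I = 0.5,
                            q_e = 0.2, q_c = 0.2, t_end = 5,
                            baseline = c("exponential", "weibull"),
                            shape = 1.5, n_reps = 10000L, seed = 1L) {
  baseline <- match.arg(baseline)
  stopifnot(length(n) == 1L, length(p_M) == 1L, length(p_T) == 1L)
  if (!is.finite(n) || n < 4 || n != round(n))
    stop("'n' must be an integer >= 4", call. = FALSE)
  for (p in c(p_M = p_M, p_T = p_T, q_e = q_e)) {
    if (!is.finite(p) || p <= 0 || p >= 1)
      stop("probabilities p_M, p_T, q_e must lie in (0, 1)", call. = FALSE)
  }
  if (!is.finite(q_c) || q_c < 0 || q_c >= 1)
    stop("'q_c' must lie in [0, 1)", call. = FALSE)
  for (h in c(or_MT = or_MT, hr_M = hr_M, hr_T = hr_T, hr_I = hr_I)) {
    if (!is.finite(h) || h <= 0)
      stop("or_MT and hazard ratios must be positive", call. = FALSE)
  }
  if (!is.finite(t_end) || t_end <= 0)
    stop("'t_end' must be positive", call. = FALSE)
  if (baseline == "weibull" && (!is.finite(shape) || shape <= 0))
    stop("Weibull 'shape' must be positive", call. = FALSE)
  if (!is.finite(n_reps) || n_reps < 1)
    stop("'n_reps' must be a positive integer", call. = FALSE)

  probs <- cell_probabilities(p_M, p_T, or_MT)  # validates feasibility
  cfg <- list(n = as.integer(n), p_M = p_M, p_T = p_T, or_MT = or_MT,
              hr_M = hr_M, hr_T = hr_T, hr_I = hr_I,
              q_e = q_e, q_c = q_c, t_end = t_end,
              baseline = baseline, shape = shape,
              n_reps = as.integer(n_reps), seed = as.integer(seed),
              cell_probs = probs)
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Simulation scenario:\n")
  cat(sprintf("  n = %d, p_M = %g, p_T = %g, OR_MT = %g\n",
              x$n, x$p_M, x$p_T, x$or_MT))
  cat(sprintf("  HR_M = %g, HR_T = %g, HR_I = %g\n", x$hr_M, x$hr_T, x$hr_I))
  cat(sprintf("  q_e = %g, q_c = %g, t_end = %g years, baseline = %s\n",
              x$q_e, x$q_c, x$t_end,
              if (x$baseline == "weibull")
                sprintf("weibull(shape = %g)", x$shape) else "exponential"))
  cat(sprintf("  n_reps = %d, seed = %d\n", x$n_reps, x$seed))
  invisible(x)
}

#' Joint cell probabilities from margins and an odds ratio
#'
#' Solves for the 2x2 joint distribution of marker M and treatment T with
#' margins `P(M = 1) = p_M`, `P(T = 1) = p_T` and odds ratio `or_MT`.
#' The constraint `or_MT * (p_M - p11) * (p_T - p11) = p11 * (1 - p_M -
#' p_T + p11)` is a quadratic in `p11 = P(M = 1, T = 1)` with a unique
#' root in the Frechet interval `(max(0, p_M + p_T - 1), min(p_M, p_T))`
#' for any finite positive odds ratio.
#'
#' @param p_M,p_T marginal probabilities, in (0, 1).
#' @param or_MT target odds ratio, positive.
#' @return Named numeric vector `c(p00, p01, p10, p11)` indexed as
#'   `p<M><T>`; strictly positive and summing to 1.
#' @examples
#' cell_probabilities(0.25, 0.5, 1)  # independence: p11 = 0.125
#' cell_probabilities(0.25, 0.5, 2)
#' @export
cell_probabilities <- function(p_M, p_T, or_MT) {
  stopifnot(is.finite(p_M), is.finite(p_T), is.finite(or_MT),
            p_M > 0, p_M < 1, p_T > 0, p_T < 1, or_MT > 0)
  lo <- max(0, p_M + p_T - 1)
  hi <- min(p_M, p_T)
  if (abs(or_MT - 1) < 1e-12) {
    p11 <- p_M * p_T
  } else {
    a <- or_MT - 1
    b <- -((or_MT - 1) * (p_M + p_T) + 1)
    cc <- or_MT * p_M * p_T
    disc <- b * b - 4 * a * cc
    if (disc < 0)
      stop("infeasible (p_M, p_T, or_MT) combination", call. = FALSE)
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    p11 <- roots[roots > lo & roots < hi]
    if (length(p11) != 1L)
      stop("infeasible (p_M, p_T, or_MT) combination", call. = FALSE)
  }
  p <- c(p00 = 1 - p_M - p_T + p11, p01 = p_T - p11,
         p10 = p_M - p11, p11 = p11)
  if (any(p <= 0))
    stop("margins and odds ratio give a degenerate cell", call. = FALSE)
  p
}

#' Exponential rate from a cumulative event fraction
#'
#' Returns the rate `lambda` such that a fraction `q` of subjects has
#' failed by time `t_end` under an exponential time-to-event law:
#' `lambda = -log(1 - q) / t_end`.
#'
#' @param q cumulative fraction by `t_end`; in (0, 1), or 0 (returns 0,
#'   used to switch off random censoring).
#' @param t_end horizon, positive.
#' @return The rate (per year if `t_end` is in years).
#' @export
rate_parameter <- function(q, t_end) {
  stopifnot(is.finite(q), is.finite(t_end), t_end > 0)
  if (q == 0) return(0)
  if (q < 0 || q >= 1)
    stop("'q' must lie in [0, 1)", call. = FALSE)
  -log(1 - q) / t_end
}

# Deterministic per-replicate substream seed: a fixed LCG-style mix of the
# master seed and replicate index, kept strictly below 2^31 so it is a
# valid R integer seed. Replicate j is reproducible in isolation.
replicate_seed <- function(seed, j) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + j) %% 2147483629)
}

#' Read a scenario configuration from a YAML file
#'
#' The file holds top-level keys matching the arguments of
#' [scenario_config()]; omitted keys take the defaults.
#'
#' @param path path to a YAML file.
#' @return A `scenario_config` object.
#' @export
read_scenario <- function(path) {
  vals <- read_yaml_plain(path)
  known <- names(formals(scenario_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown scenario fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(scenario_config, vals)
}

# YAML 1.1 would otherwise read the bare key `n` as a boolean; keep
# yes/no-like tokens verbatim (no field in our schemas is logical).
read_yaml_plain <- function(path) {
  yaml::yaml.load_file(path, handlers = list(
    "bool#yes" = function(x) x, "bool#no" = function(x) x))
}
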
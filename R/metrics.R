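#' Eligibility rule for a replicate dataset
#'
#' A simulated dataset enters the performance summaries only when events
#' occurred in at least three of the four marker-by-treatment cells;
#' otherwise neither parametrization can separate the treatment effects
#' by marker level.
#'
#' @param x a `cohort_data` data frame, or a length-4 vector of per-cell
#'   event counts.
#' @return `TRUE` when at least three cells have at least one event.
#' @export
eligibility <- function(x) {
  counts <- if (inherits(x, "cohort_data")) cell_event_counts(x)
            else as.numeric(x)
  stopifnot(length(counts) == 4L)
  sum(counts >= 1) >= 3L
}

#' Summarize replicate fits into performance measures
#'
#' Computes, per method and coefficient, the Monte-Carlo performance
#' measures used to evaluate interaction estimators: bias (and relative
#' bias in percent when the true value is nonzero), the empirical
#' standard error `EmpSE` (SD of estimates, `N_c - 1` denominator), the
#' model-based standard error `ModSE` (root mean of model variances),
#' the relative percent error `100 * (ModSE / EmpSE - 1)`, coverage of
#' the Wald and profile-likelihood 95% intervals, and power (or type-I
#' error when the true value is zero) of the Wald and PL tests at
#' `alpha`.
#'
#' All measures are computed over eligible replicates with a converged
#' fit (`N_c`). PL-based coverage and power additionally require both PL
#' bounds to have converged; their denominator `N_c_pl` is reported
#' alongside.
#'
#' @param records a data frame of replicate records as produced by
#'   [run_scenario()]: one row per replicate x method x coefficient with
#'   columns `method`, `coefficient`, `estimate`, `variance`, `wald_lower`,
#'   `wald_upper`, `pl_lower`, `pl_upper`, `pl_lower_conv`,
#'   `pl_upper_conv`, `p_wald`, `p_pl`, `eligible`, `converged`,
#'   `n_events`.
#' @param truth named vector of true coefficient values, e.g.
#'   `c(I = log(0.5), TM_low = 0, TM_high = log(0.5))`.
#' @param alpha significance level of the tests.
#' @return A data frame with one row per method x coefficient.
#' @export
summarize_performance <- function(records, truth, alpha = 0.05) {
  stopifnot(is.data.frame(records), !is.null(names(truth)))
  keys <- unique(records[, c("method", "coefficient")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    m <- keys$method[i]; cf <- keys$coefficient[i]
    r <- records[records$method == m & records$coefficient == cf, ]
    if (!cf %in% names(truth))
      stop("no true value supplied for coefficient ", cf, call. = FALSE)
    tv <- truth[[cf]]
    use <- r$eligible & r$converged & is.finite(r$estimate)
    r <- r[use, ]
    n_c <- nrow(r)
    if (n_c == 0L)
      stop("no eligible converged replicates for ", m, "/", cf,
           call. = FALSE)
    est <- r$estimate
    bias <- mean(est) - tv
    rel_bias_pct <- if (tv != 0) 100 * bias / abs(tv) else NA_real_
    emp_se <- stats::sd(est)
    mod_se <- sqrt(mean(r$variance))
    cover_wald <- 100 * mean(r$wald_lower <= tv & tv <= r$wald_upper)
    rej_wald <- 100 * mean(r$p_wald <= alpha)
    pl_ok <- !is.na(r$pl_lower_conv) & !is.na(r$pl_upper_conv) &
      r$pl_lower_conv == 1 & r$pl_upper_conv == 1
    n_pl <- sum(pl_ok)
    cover_pl <- if (n_pl)
      100 * mean(r$pl_lower[pl_ok] <= tv & tv <= r$pl_upper[pl_ok])
      else NA_real_
    rej_pl <- if (n_pl)
      100 * mean(r$pl_lower[pl_ok] > 0 | r$pl_upper[pl_ok] < 0)
      else NA_real_
    data.frame(method = m, coefficient = cf, truth = tv,
               bias = bias, rel_bias_pct = rel_bias_pct,
               emp_se = emp_se, mod_se = mod_se,
               rel_err_mod_se_pct = 100 * (mod_se / emp_se - 1),
               coverage_wald_pct = cover_wald,
               coverage_pl_pct = cover_pl,
               power_wald_pct = rej_wald, power_pl_pct = rej_pl,
               measure = if (tv == 0) "type1" else "power",
               n_c = n_c, n_c_pl = n_pl,
               mean_events = mean(r$n_events))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
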
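#' Treated fraction of the risk set at a given time
#'
#' `p_e` is the fraction of subjects in the full cohort still at risk at
#' time `t` who were assigned to the experimental arm. A subject is at
#' risk at `t` when its follow-up time is `>= t`, so a case failing at
#' `t` is a member of its own risk set.
#'
#' @param cohort a `cohort_data` data frame.
#' @param t a positive time.
#' @return The proportion treated among subjects at risk, in `[0, 1]`.
#' @export
risk_set_fraction <- function(cohort, t) {
  stopifnot(is.finite(t), t > 0)
  at_risk <- cohort$time >= t
  n_risk <- sum(at_risk)
  if (n_risk == 0L)
    stop("empty risk set at t = ", format(t), call. = FALSE)
  sum(cohort$T[at_risk]) / n_risk
}

#' Build the case-only analysis dataset from a cohort
#'
#' Restricts the cohort to cases (subjects with an observed event) and
#' attaches each case's offset `log(p_e / (1 - p_e))`, where `p_e` is the
#' treated fraction of the full-cohort risk set at the case's own event
#' time ([risk_set_fraction()]). The offset encodes the treatment-arm
#' composition of the risk set, so the logistic regression of treatment
#' on marker among cases estimates the interaction without measuring the
#' marker in non-cases. Offsets use only treatment assignments and
#' follow-up times, never the marker.
#'
#' Cases with a degenerate risk set (`p_e` 0 or 1, infinite offset) carry
#' no information for the logistic fit; they are dropped and counted in
#' the `n_degenerate` attribute.
#'
#' Tied event times share one risk set evaluated at the common time.
#'
#' @param cohort a `cohort_data` data frame with at least one event.
#' @return A data frame of class `caseonly_data` with columns `id`, `M`,
#'   `T`, `t_e`, `offset`, `M_low`, `M_high`; attributes `n_cases`
#'   (events in the cohort) and `n_degenerate` (cases dropped).
#' @examples
#' coh <- generate_cohort(scenario_config(n = 300), seed = 7)
#' co <- build_case_only(coh)
#' head(co)
#' @export
build_case_only <- function(cohort) {
  cases <- which(cohort$event == 1L)
  if (length(cases) == 0L)
    stop("cohort has no events; case-only dataset is empty", call. = FALSE)
  t_e <- cohort$time[cases]

  # risk-set composition at each distinct event time, case included
  ord <- order(cohort$time)
  times_sorted <- cohort$time[ord]
  treated_sorted <- cohort$T[ord]
  n <- length(times_sorted)
  # subjects at risk at t: follow-up >= t -> suffix of the sorted order
  first_idx <- findInterval(t_e, times_sorted, left.open = TRUE) + 1L
  n_risk <- n - first_idx + 1L
  treated_tail <- rev(cumsum(rev(treated_sorted)))
  n_treated <- treated_tail[first_idx]
  p_e <- n_treated / n_risk

  degenerate <- p_e <= 0 | p_e >= 1
  out <- data.frame(id = cohort$id[cases], M = cohort$M[cases],
                    T = cohort$T[cases], t_e = t_e,
                    offset = log(p_e / (1 - p_e)))
  if (any(degenerate)) {
    warning(sum(degenerate),
            " case(s) with degenerate risk set (p_e 0 or 1) dropped",
            call. = FALSE)
    out <- out[!degenerate, , drop = FALSE]
  }
  out$M_low <- 1L - out$M
  out$M_high <- out$M
  rownames(out) <- NULL
  class(out) <- c("caseonly_data", "data.frame")
  attr(out, "n_cases") <- length(cases)
  attr(out, "n_degenerate") <- sum(degenerate)
  out
}

#' Write a case-only dataset as CSV
#'
#' Columns `id`, `M`, `T`, `t_e`, `offset`.
#'
#' @param caseonly a `caseonly_data` data frame.
#' @param path file path.
#' @export
write_case_only <- function(caseonly, path) {
  utils::write.csv(
    as.data.frame(caseonly)[, c("id", "M", "T", "t_e", "offset")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
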
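#' Simulate one cohort under a scenario configuration
#'
#' Assigns each of `n` subjects independently to one of the four
#' marker-by-treatment cells with probabilities implied by
#' (`p_M`, `p_T`, `or_MT`), draws an event time by inverse-CDF sampling
#' from the proportional-hazards model, draws an independent
#' non-administrative censoring time from the same family with all
#' covariate effects set to zero (censoring is non-differential by
#' construction), and applies administrative censoring at `t_end`.
#'
#' A subject is an event at `t_e` if `t_e < min(t_c, t_end)` and is
#' otherwise censored at `min(t_c, t_end)`.
#'
#' @param config a [scenario_config()] object.
#' @param seed optional integer seed set before drawing; `NULL` uses the
#'   current RNG state.
#' @return A data frame of class `cohort_data` with columns `id`, `M`,
#'   `T`, `time` (years), `event` (0/1).
#' @examples
#' coh <- generate_cohort(scenario_config(n = 200), seed = 1)
#' table(coh$M, coh$T)
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  probs <- config$cell_probs
  cell <- sample.int(4L, n, replace = TRUE, prob = probs)
  # cells ordered p00, p01, p10, p11 -> M = cell in {3,4}, T = cell in {2,4}
  M <- as.integer(cell >= 3L)
  TT <- as.integer(cell == 2L | cell == 4L)

  eta <- log(config$hr_M) * M + log(config$hr_T) * TT +
    log(config$hr_I) * M * TT
  u_e <- stats::runif(n)
  u_c <- stats::runif(n)

  if (config$baseline == "exponential") {
    lambda_e <- rate_parameter(config$q_e, config$t_end)
    t_e <- -log(u_e) / (lambda_e * exp(eta))
  } else {
    k <- config$shape
    # scale so the reference-cell event fraction at t_end is q_e
    b <- config$t_end / (-log(1 - config$q_e))^(1 / k)
    t_e <- b * (-log(u_e) / exp(eta))^(1 / k)
  }
  if (config$q_c > 0) {
    lambda_c <- rate_parameter(config$q_c, config$t_end)
    t_c <- -log(u_c) / lambda_c
  } else {
    t_c <- rep(Inf, n)
  }

  horizon <- pmin(t_c, config$t_end)
  event <- as.integer(t_e < horizon)
  time <- ifelse(event == 1L, t_e, horizon)

  out <- data.frame(id = seq_len(n), M = M, T = TT,
                    time = time, event = event)
  class(out) <- c("cohort_data", "data.frame")
  attr(out, "t_end") <- config$t_end
  out
}

#' Coerce a subject table to a cohort dataset
#'
#' Validates a per-subject table (columns `M`, `T`, `time`, `event`;
#' `id` added if missing) for use with [build_case_only()] and
#' [fit_cox()].
#'
#' @param x a data frame.
#' @return A `cohort_data` data frame.
#' @export
as_cohort <- function(x) {
  x <- as.data.frame(x)
  need <- c("M", "T", "time", "event")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"id" %in% names(x)) x$id <- seq_len(nrow(x))
  if (!all(x$M %in% 0:1) || !all(x$T %in% 0:1))
    stop("'M' and 'T' must be binary 0/1", call. = FALSE)
  if (!all(x$event %in% 0:1))
    stop("'event' must be binary 0/1", call. = FALSE)
  if (any(!is.finite(x$time)) || any(x$time <= 0))
    stop("'time' must be positive and finite", call. = FALSE)
  x <- x[, c("id", "M", "T", "time", "event")]
  class(x) <- c("cohort_data", "data.frame")
  x
}

#' Write / read a cohort as delimited text
#'
#' CSV with header `id,M,T,time,event`; times in years.
#'
#' @param cohort a `cohort_data` data frame.
#' @param path file path.
#' @return `read_cohort` returns a validated `cohort_data` data frame;
#'   `write_cohort` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, c("id", "M", "T", "time", "event")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  as_cohort(utils::read.csv(path))
}

# Per-cell event counts of a cohort, as a 4-vector in (M,T) order
# (00, 01, 10, 11); used by the eligibility rule.
cell_event_counts <- function(cohort) {
  idx <- 1L + cohort$T + 2L * cohort$M
  counts <- tabulate(idx[cohort$event == 1L], nbins = 4L)
  names(counts) <- c("e00", "e01", "e10", "e11")
  counts
}
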
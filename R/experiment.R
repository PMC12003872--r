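#' Run one simulation scenario
#'
#' Generates `config$n_reps` replicate cohorts (each from its own seed
#' substream, so any replicate is reproducible in isolation), applies
#' the eligibility rule, builds the case-only dataset, fits the
#' requested models, and reduces the replicate records to performance
#' measures with [summarize_performance()].
#'
#' Methods: `caseonly_firth` (offset logistic with Firth penalization on
#' cases only), `caseonly_ml` (same without penalization), `cox_firth`
#' (full-cohort Firth-penalized Cox with the solver settings `max_iter
#' 1000`, `max_step 0.01`). The `interaction` parametrization records the
#' interaction coefficient `I`; the `subgroup` parametrization records
#' the per-marker-level treatment coefficients `TM_low` and `TM_high`.
#'
#' @param config a [scenario_config()].
#' @param methods character vector of methods to fit.
#' @param parametrizations character vector among `"interaction"`,
#'   `"subgroup"`.
#' @param ci `"wald"`, `"pl"` or `"both"`; profile-likelihood intervals
#'   are computed only for the recorded coefficients.
#' @param alpha significance level for the power / type-I error
#'   measures.
#' @return A list with `records` (one row per replicate x method x
#'   coefficient), `summary` (from [summarize_performance()]), `truth`,
#'   and `counts` (ineligible replicates, non-converged fits, degenerate
#'   offsets).
#' @examples
#' cfg <- scenario_config(n = 200, n_reps = 20, seed = 42)
#' res <- run_scenario(cfg, methods = "caseonly_firth", ci = "wald")
#' res$summary
#' @export
run_scenario <- function(config,
                         methods = c("caseonly_firth", "caseonly_ml",
                                     "cox_firth"),
                         parametrizations = "interaction",
                         ci = c("both", "wald", "pl"), alpha = 0.05) {
  stopifnot(inherits(config, "scenario_config"))
  ci <- match.arg(ci)
  known <- c("caseonly_firth", "caseonly_ml", "cox_firth")
  if (length(methods) == 0L || !all(methods %in% known))
    stop("'methods' must be a non-empty subset of: ",
         paste(known, collapse = ", "), call. = FALSE)
  stopifnot(all(parametrizations %in% c("interaction", "subgroup")),
            length(parametrizations) >= 1L)

  truth <- c(I = log(config$hr_I), TM_low = log(config$hr_T),
             TM_high = log(config$hr_T) + log(config$hr_I))
  n_ineligible <- 0L
  n_degenerate <- 0L
  rec_list <- vector("list", config$n_reps)

  for (j in seq_len(config$n_reps)) {
    cohort <- generate_cohort(config, seed = replicate_seed(config$seed, j))
    n_events <- sum(cohort$event)
    eligible <- n_events > 0L && eligibility(cohort)
    if (!eligible) {
      n_ineligible <- n_ineligible + 1L
      next
    }
    caseonly_data <- NULL
    if (any(methods != "cox_firth")) {
      caseonly_data <- withCallingHandlers(
        build_case_only(cohort),
        warning = function(w) invokeRestart("muffleWarning"))
      n_degenerate <- n_degenerate + attr(caseonly_data, "n_degenerate")
    }
    rows <- list()
    for (m in methods) for (par in parametrizations) {
      rows[[length(rows) + 1L]] <-
        fit_one(m, par, cohort, caseonly_data, ci, config)
    }
    rec <- do.call(rbind, rows)
    rec$j <- j
    rec$eligible <- TRUE
    rec$n_events <- n_events
    rec_list[[j]] <- rec
  }
  records <- do.call(rbind, rec_list)
  if (is.null(records))
    stop("no eligible replicates in this scenario", call. = FALSE)
  summary <- summarize_performance(records, truth, alpha = alpha)
  fit_key <- paste(records$j, records$method, records$parametrization)
  list(records = records, summary = summary, truth = truth,
       counts = c(n_reps = config$n_reps, ineligible = n_ineligible,
                  degenerate_offsets = n_degenerate,
                  nonconverged = length(unique(fit_key[!records$converged]))))
}

# Fit one method/parametrization on one replicate and flatten the
# recorded coefficients into record rows. Errors become non-converged
# rows so a scenario run never aborts on a single replicate.
fit_one <- function(method, parametrization, cohort, caseonly_data, ci,
                    config) {
  want_pl <- ci %in% c("pl", "both")
  coefs <- if (parametrization == "interaction") "I"
           else c("TM_low", "TM_high")
  empty <- data.frame(method = method, parametrization = parametrization,
                      coefficient = coefs, estimate = NA_real_,
                      variance = NA_real_, wald_lower = NA_real_,
                      wald_upper = NA_real_, pl_lower = NA_real_,
                      pl_upper = NA_real_, pl_lower_conv = NA_real_,
                      pl_upper_conv = NA_real_, p_wald = NA_real_,
                      p_pl = NA_real_, converged = FALSE)
  fit <- tryCatch({
    if (method == "cox_firth") {
      fit_cox(cohort, parametrization, firth = TRUE, pl = FALSE)
    } else {
      X <- if (parametrization == "interaction")
        cbind(gamma_T = 1, I = caseonly_data$M)
      else cbind(TM_low = caseonly_data$M_low,
                 TM_high = caseonly_data$M_high)
      fit_logistic(X, caseonly_data$T, offset = caseonly_data$offset,
                   firth = (method == "caseonly_firth"), pl = FALSE)
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(empty)

  # model coefficient names behind the recorded names
  map <- c(I = if (method == "cox_firth") "MT" else "I",
           TM_low = "TM_low", TM_high = "TM_high")
  out <- empty
  out$converged <- fit$converged
  for (i in seq_along(coefs)) {
    nm <- map[[coefs[i]]]
    k <- match(nm, names(fit$coefficients))
    out$estimate[i] <- fit$coefficients[k]
    out$variance[i] <- fit$vcov[k, k]
    out$wald_lower[i] <- fit$wald_ci[k, "lower"]
    out$wald_upper[i] <- fit$wald_ci[k, "upper"]
    out$p_wald[i] <- fit$p_wald[k]
    if (want_pl && fit$converged) {
      pc <- tryCatch(profile_ci(fit, nm), error = function(e) NULL)
      if (!is.null(pc)) {
        out$pl_lower[i] <- pc[["lower"]]
        out$pl_upper[i] <- pc[["upper"]]
        out$pl_lower_conv[i] <- pc[["lower_conv"]]
        out$pl_upper_conv[i] <- pc[["upper_conv"]]
      }
      out$p_pl[i] <- tryCatch(lr_test(fit, nm),
                              error = function(e) NA_real_)
    }
  }
  out
}

#' Scenario grid specification
#'
#' Cartesian grid of generator settings, one [run_scenario()] call per
#' combination. The defaults are the full study grid: n in
#' \{200, 300, 400, 500, 600, 800, 1000\}, p_M in \{0.25, 0.5, 0.75\},
#' HR_M in \{0.6, 0.8, 1, 3, 6\}, OR_MT in \{0.5, 1, 2\}, HR_I in
#' \{0.25, 0.5, 0.75, 1\}, with p_T = 0.5, q_e = q_c = 0.2, t_end = 5
#' years, HR_T = 1 and 10000 replicates per scenario. `n_reps` is the
#' knob to scale a desk-size reproduction down.
#'
#' @param n,p_M,hr_M,or_MT,hr_I vectors of varied settings.
#' @param p_T,q_e,q_c,t_end,hr_T fixed settings.
#' @param n_reps replicates per scenario.
#' @param seed master seed; each scenario derives its own seed from the
#'   master seed and its settings, so results do not depend on grid
#'   order.
#' @param methods,parametrizations,ci passed to [run_scenario()].
#' @param out_dir optional directory for per-scenario summary CSVs;
#'   scenarios whose CSV already exists are skipped (resumable runs).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n = c(200, 300, 400, 500, 600, 800, 1000),
                      p_M = c(0.25, 0.5, 0.75),
                      hr_M = c(0.6, 0.8, 1, 3, 6),
                      or_MT = c(0.5, 1, 2),
                      hr_I = c(0.25, 0.5, 0.75, 1),
                      p_T = 0.5, q_e = 0.2, q_c = 0.2, t_end = 5,
                      hr_T = 1, n_reps = 10000L, seed = 1L,
                      methods = c("caseonly_firth", "cox_firth"),
                      parametrizations = "interaction",
                      ci = "both", out_dir = NULL) {
  spec <- list(n = n, p_M = p_M, hr_M = hr_M, or_MT = or_MT, hr_I = hr_I,
               p_T = p_T, q_e = q_e, q_c = q_c, t_end = t_end,
               hr_T = hr_T, n_reps = as.integer(n_reps),
               seed = as.integer(seed), methods = methods,
               parametrizations = parametrizations, ci = ci,
               out_dir = out_dir)
  class(spec) <- "grid_spec"
  spec
}

#' Read a grid specification from YAML
#'
#' Top-level keys match the arguments of [grid_spec()].
#'
#' @param path path to a YAML file.
#' @return A `grid_spec` object.
#' @export
read_grid <- function(path) {
  vals <- read_yaml_plain(path)
  known <- names(formals(grid_spec))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown grid fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(grid_spec, vals)
}

# Settings-keyed scenario seed: a fixed mix of the master seed and the
# varied scenario settings, so a scenario's result is invariant to its
# position in (or the shuffling of) the grid.
scenario_seed <- function(seed, n, p_M, hr_M, or_MT, hr_I) {
  mix <- (as.double(seed) %% 2147483647) * 48271 +
    n * 7919 + round(p_M * 1e4) * 104729 + round(hr_M * 1e4) * 1299709 +
    round(or_MT * 1e4) * 15485863 + round(hr_I * 1e4) * 32452843
  as.integer(mix %% 2147483629)
}

#' Run a scenario grid
#'
#' Executes [run_scenario()] for every combination in the grid and
#' row-binds the per-scenario summaries, tagging each row with its
#' generator settings. Each scenario derives its seed from the master
#' seed and its own settings (not its grid position), so shuffling the
#' grid does not change any scenario's result. When `out_dir` is set,
#' each scenario's summary is written as CSV and existing files are
#' skipped.
#'
#' @param grid a [grid_spec()].
#' @param verbose print one line per scenario.
#' @return A data frame: scenario settings + performance summary rows.
#' @export
run_grid <- function(grid, verbose = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  combos <- expand.grid(n = grid$n, p_M = grid$p_M, hr_M = grid$hr_M,
                        or_MT = grid$or_MT, hr_I = grid$hr_I,
                        KEEP.OUT.ATTRS = FALSE)
  if (!is.null(grid$out_dir) && !dir.exists(grid$out_dir))
    dir.create(grid$out_dir, recursive = TRUE)
  out <- vector("list", nrow(combos))
  for (s in seq_len(nrow(combos))) {
    cm <- combos[s, ]
    tag <- sprintf("n%d_pM%g_hrM%g_orMT%g_hrI%g",
                   cm$n, cm$p_M, cm$hr_M, cm$or_MT, cm$hr_I)
    csv <- if (!is.null(grid$out_dir))
      file.path(grid$out_dir, paste0(tag, ".csv")) else NULL
    if (!is.null(csv) && file.exists(csv)) {
      out[[s]] <- utils::read.csv(csv)
      next
    }
    cfg <- scenario_config(n = cm$n, p_M = cm$p_M, p_T = grid$p_T,
                           or_MT = cm$or_MT, hr_M = cm$hr_M,
                           hr_T = grid$hr_T, hr_I = cm$hr_I,
                           q_e = grid$q_e, q_c = grid$q_c,
                           t_end = grid$t_end, n_reps = grid$n_reps,
                           seed = scenario_seed(grid$seed, cm$n, cm$p_M,
                                                cm$hr_M, cm$or_MT, cm$hr_I))
    res <- run_scenario(cfg, methods = grid$methods,
                        parametrizations = grid$parametrizations,
                        ci = grid$ci)
    smry <- cbind(cm, res$summary, row.names = NULL)
    if (!is.null(csv)) utils::write.csv(smry, csv, row.names = FALSE)
    if (verbose)
      cat(sprintf("[%d/%d] %s done\n", s, nrow(combos), tag))
    out[[s]] <- smry
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
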
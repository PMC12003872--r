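#' Cox proportional-hazards fit with optional Firth-type penalization
#'
#' Fits the full-cohort Cox model in one of two parametrizations of the
#' marker-treatment structure:
#' \describe{
#'   \item{interaction}{`h(t) = h0(t) exp(beta_M M + beta_T T + beta_I MT)`;
#'     `beta_I` is the log interaction hazard ratio.}
#'   \item{subgroup}{`h(t) = h0(t) exp(beta_M M + beta_TMlow TM_low +
#'     beta_TMhigh TM_high)` with `TM_low = T (1 - M)` and
#'     `TM_high = T M`: per-subgroup treatment effects. The interaction
#'     coefficient equals `beta_TMhigh - beta_TMlow`.}
#' }
#'
#' With `firth = TRUE` the Jeffreys-penalized partial likelihood
#' `l(beta) + 0.5 * log det I(beta)` is maximized, where `I` is the
#' partial-likelihood information; this removes leading small-sample bias
#' and yields finite estimates under monotone likelihood (for instance a
#' covariate pattern with no events). Newton steps use the penalized
#' score, are rescaled so no element exceeds `max_step`, and are halved while
#' the penalized objective worsens. Ties are handled with the Breslow
#' approximation. Standard errors come from the inverse information at
#' the optimum.
#'
#' @param cohort a `cohort_data` data frame (or anything [as_cohort()]
#'   accepts) with at least one event.
#' @param parametrization `"interaction"` or `"subgroup"`.
#' @param firth logical; apply the Jeffreys penalization.
#' @param pl logical; compute profile-likelihood intervals and
#'   penalized-LR p-values for every coefficient.
#' @param level confidence level for intervals.
#' @param max_iter maximum Newton iterations.
#' @param max_step cap on the largest element of each Newton step, on
#'   the log-hazard-ratio scale.
#' @param tol convergence tolerance on the max-norm of the penalized
#'   score.
#' @return An object of class `firth_cox` with the same fields as
#'   [fit_logistic()] results (`coefficients`, `se`, `vcov`, `loglik`,
#'   `converged`, `iterations`, `wald_ci`, `pl_ci`, `p_wald`, `p_pl`).
#' @examples
#' coh <- generate_cohort(scenario_config(n = 400), seed = 3)
#' fit_cox(coh, "interaction", firth = TRUE, pl = FALSE)
#' @export
fit_cox <- function(cohort, parametrization = c("interaction", "subgroup"),
                    firth = TRUE, pl = TRUE, level = 0.95,
                    max_iter = 1000L, max_step = 0.01, tol = 1e-6) {
  parametrization <- match.arg(parametrization)
  cohort <- as_cohort(cohort)
  if (sum(cohort$event) == 0L)
    stop("cohort has no events", call. = FALSE)
  X <- cox_design(cohort, parametrization)
  if (qr(X)$rank < ncol(X))
    stop("design columns are collinear", call. = FALSE)
  ctx <- cox_context(X, cohort$time, cohort$event)

  fit <- cox_core(ctx, firth = firth, fixed = integer(0), at = numeric(0),
                  start = rep(0, ncol(X)), max_iter = max_iter,
                  max_step = max_step, tol = tol)
  nm <- colnames(X)
  se <- sqrt(diag(fit$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  wald_ci <- cbind(lower = fit$beta - z * se, upper = fit$beta + z * se)
  rownames(wald_ci) <- nm
  out <- list(coefficients = stats::setNames(fit$beta, nm),
              se = stats::setNames(se, nm), vcov = fit$vcov,
              loglik = fit$loglik, converged = fit$converged,
              iterations = fit$iterations, wald_ci = wald_ci,
              pl_ci = NULL,
              p_wald = stats::setNames(2 * stats::pnorm(-abs(fit$beta / se)),
                                       nm),
              p_pl = NULL, firth = firth, level = level,
              parametrization = parametrization, ctx = ctx,
              max_iter = max_iter, max_step = max_step, tol = tol,
              n = nrow(cohort), n_events = sum(cohort$event))
  class(out) <- "firth_cox"
  if (pl && fit$converged) {
    out$pl_ci <- do.call(rbind, lapply(nm, function(x)
      profile_ci(out, x, level = level)))
    rownames(out$pl_ci) <- nm
    out$p_pl <- vapply(nm, function(x) lr_test(out, x), 0)
  }
  out
}

#' @export
coef.firth_cox <- function(object, ...) object$coefficients

#' @export
vcov.firth_cox <- function(object, ...) object$vcov

#' @export
logLik.firth_cox <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
print.firth_cox <- function(x, ...) {
  cat(sprintf("%s Cox model (%s parametrization), %d subjects, %d events\n",
              if (x$firth) "Firth-penalized" else "Maximum-likelihood",
              x$parametrization, x$n, x$n_events))
  tab <- cbind(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
               se = x$se, `wald lo` = x$wald_ci[, 1],
               `wald hi` = x$wald_ci[, 2])
  if (!is.null(x$pl_ci))
    tab <- cbind(tab, `pl lo` = x$pl_ci[, "lower"],
                 `pl hi` = x$pl_ci[, "upper"])
  print(round(tab, 4))
  cat(sprintf("partial loglik%s = %.4f, converged = %s (%d iterations)\n",
              if (x$firth) " (penalized)" else "", x$loglik,
              x$converged, x$iterations))
  invisible(x)
}

cox_design <- function(cohort, parametrization) {
  if (parametrization == "interaction") {
    cbind(M = cohort$M, T = cohort$T, MT = cohort$M * cohort$T)
  } else {
    cbind(M = cohort$M, TM_low = cohort$T * (1 - cohort$M),
          TM_high = cohort$T * cohort$M)
  }
}

# Precompute the risk-set structure once per dataset. Rows are collapsed
# to unique covariate patterns (at most 4 here), so every likelihood,
# score and information evaluation reduces to small matrix products of
# an events-by-patterns risk-count matrix with pattern weights.
cox_context <- function(X, time, event) {
  pat <- unique(X)
  g <- match(apply(X, 1L, paste, collapse = "\r"),
             apply(pat, 1L, paste, collapse = "\r"))
  G <- nrow(pat)
  ord <- order(time, decreasing = TRUE)
  t_sorted <- time[ord]
  g_sorted <- g[ord]
  # cumulative pattern counts over the descending-time order
  counts <- vapply(seq_len(G), function(k) cumsum(g_sorted == k),
                   numeric(length(time)))
  ev_idx <- which(event[ord] == 1L)
  t_ev <- t_sorted[ev_idx]
  # Breslow risk set at an event time t: everyone with time >= t,
  # i.e. the full tie group in the descending order
  last_tie <- vapply(ev_idx, function(i) {
    j <- i
    while (j < length(t_sorted) && t_sorted[j + 1L] == t_sorted[i]) j <- j + 1L
    j
  }, 1L)
  C <- counts[last_tie, , drop = FALSE]         # events x patterns
  list(X = pat, C = C, g_ev = g_sorted[ev_idx], p = ncol(X), G = G,
       n_events = length(ev_idx))
}

# Partial log-likelihood, score and information from the collapsed
# representation; any subset can be requested.
cox_eval <- function(ctx, beta, what = c("loglik", "score", "info")) {
  Xp <- ctx$X
  w <- drop(exp(Xp %*% beta))
  S0 <- drop(ctx$C %*% w)
  out <- list()
  if ("loglik" %in% what) {
    out$loglik <- sum(drop(Xp %*% beta)[ctx$g_ev]) - sum(log(S0))
  }
  p <- ctx$p
  if (any(c("score", "info") %in% what)) {
    S1 <- ctx$C %*% (w * Xp)                     # events x p
    Ebar <- S1 / S0
    if ("score" %in% what) {
      out$score <- colSums(Xp[ctx$g_ev, , drop = FALSE] - Ebar)
    }
    if ("info" %in% what) {
      I <- matrix(0, p, p)
      for (j in seq_len(p)) for (k in j:p) {
        S2jk <- drop(ctx$C %*% (w * Xp[, j] * Xp[, k]))
        I[j, k] <- I[k, j] <- sum(S2jk / S0 - Ebar[, j] * Ebar[, k])
      }
      out$info <- I
    }
  }
  out
}

cox_logdet_info <- function(ctx, beta) {
  I <- cox_eval(ctx, beta, "info")$info
  d <- determinant(I)
  if (d$sign <= 0) return(-Inf)
  d$modulus[1]
}

cox_penloglik <- function(ctx, beta, firth) {
  ll <- cox_eval(ctx, beta, "loglik")$loglik
  if (firth) ll <- ll + 0.5 * cox_logdet_info(ctx, beta)
  ll
}

# Central finite-difference gradient of 0.5 * log det I(beta); the
# penalty's curvature is ignored in the Newton direction (information
# only), as is standard for penalized partial likelihood solvers.
cox_pen_grad <- function(ctx, beta, h = 1e-4) {
  p <- length(beta)
  gr <- numeric(p)
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- h
    gr[j] <- (cox_logdet_info(ctx, beta + e) -
                cox_logdet_info(ctx, beta - e)) / (4 * h)
  }
  gr
}

# Constrained Newton maximizer of the (penalized) partial likelihood
# with the step length capped at max_step; `fixed` coefficients held
# at `at`.
cox_core <- function(ctx, firth, fixed, at, start, max_iter = 1000L,
                     max_step = 0.01, tol = 1e-6) {
  p <- ctx$p
  free <- setdiff(seq_len(p), fixed)
  beta <- start
  beta[fixed] <- at
  ll <- cox_penloglik(ctx, beta, firth)
  converged <- length(free) == 0L  # fully constrained: nothing to optimize
  iter <- 0L
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    ev <- cox_eval(ctx, beta, c("score", "info"))
    score <- ev$score
    if (firth) score <- score + cox_pen_grad(ctx, beta)
    if (max(abs(score[free])) < tol) { converged <- TRUE; break }
    delta <- rep(0, p)
    sub <- tryCatch(solve(ev$info[free, free, drop = FALSE], score[free]),
                    error = function(e) NULL)
    if (is.null(sub)) { sub <- sign(score[free]) * max_step }
    # rescale the whole step so its largest element is max_step; a
    # uniform rescale keeps the Newton direction (and thus ascent)
    big <- max(abs(sub))
    if (big > max_step) sub <- sub * (max_step / big)
    delta[free] <- sub
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- cox_penloglik(ctx, cand, firth)
      if (is.finite(ll_new) && ll_new >= ll - 1e-10) break
      step <- step / 2
      if (step < 1e-10) { cand <- beta; ll_new <- ll; break }
    }
    if (max(abs(cand - beta)) < 1e-12 && !firth) break
    beta <- cand
    ll <- ll_new
  }
  info <- cox_eval(ctx, beta, "info")$info
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  list(beta = beta, loglik = cox_penloglik(ctx, beta, firth), vcov = vc,
       converged = converged && (iter < max_iter || max_iter == 0L),
       iterations = iter)
}

#' @export
profile_ci.firth_cox <- function(object, name, level = 0.95,
                                 max_eval = 200L) {
  k <- match(name, names(object$coefficients))
  if (is.na(k)) stop("unknown coefficient: ", name, call. = FALSE)
  est <- object$coefficients[k]
  start <- object$coefficients
  prof <- function(b) {
    fit <- cox_core(object$ctx, firth = object$firth, fixed = k, at = b,
                    start = start, max_iter = object$max_iter,
                    max_step = object$max_step, tol = object$tol)
    if (!fit$converged) return(NA_real_)
    start <<- fit$beta
    fit$loglik
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- pl_bound(prof, est, est - z * object$se[k], object$loglik,
                 level, max_eval)
  start <- object$coefficients
  hi <- pl_bound(prof, est, est + z * object$se[k], object$loglik,
                 level, max_eval)
  c(lower = unname(lo["bound"]), upper = unname(hi["bound"]),
    lower_conv = unname(lo["conv"]), upper_conv = unname(hi["conv"]))
}

#' @export
lr_test.firth_cox <- function(object, name) {
  k <- match(name, names(object$coefficients))
  if (is.na(k)) stop("unknown coefficient: ", name, call. = FALSE)
  fit0 <- cox_core(object$ctx, firth = object$firth, fixed = k, at = 0,
                   start = object$coefficients,
                   max_iter = object$max_iter, max_step = object$max_step,
                   tol = object$tol)
  if (!fit0$converged) return(NA_real_)
  dev <- max(0, 2 * (object$loglik - fit0$loglik))
  stats::pchisq(dev, df = 1, lower.tail = FALSE)
}
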
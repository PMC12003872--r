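#' Profile-likelihood confidence interval for one coefficient
#'
#' Each bound `b` solves `2 * (l*(max) - l*_profile(b)) = qchisq(level, 1)`,
#' where `l*` is the fit's (penalized) log-likelihood and `l*_profile(b)`
#' its maximum over all other coefficients with the named coefficient
#' held at `b`. Roots are found by monotone bracketing outward from the
#' Wald bound followed by [stats::uniroot()]; a bound whose bracket or
#' root search fails within the evaluation budget is returned as computed
#' but flagged unconverged.
#'
#' @param object a fitted `firth_logit` or `firth_cox` model.
#' @param name coefficient name.
#' @param level confidence level.
#' @param max_eval profile-evaluation budget per bound.
#' @return Numeric vector `c(lower, upper, lower_conv, upper_conv)`; the
#'   flags are 1 for a converged bound, 0 otherwise.
#' @export
profile_ci <- function(object, name, level = 0.95, max_eval = 200L) {
  UseMethod("profile_ci")
}

#' Penalized likelihood-ratio test of a single coefficient
#'
#' p-value for the null that the named coefficient is zero, from the
#' (penalized) likelihood-ratio statistic
#' `2 * (l*(max) - l*_profile(0))` referred to chi-squared with 1 df.
#' Dual to the profile-likelihood interval: p <= alpha exactly when the
#' PL interval at level 1 - alpha excludes zero (up to root-finder
#' tolerance).
#'
#' @inheritParams profile_ci
#' @return A p-value in `[0, 1]`, or `NA` if the constrained fit failed.
#' @export
lr_test <- function(object, name) {
  UseMethod("lr_test")
}

# Shared root-finding for a PL bound. `prof` maps a fixed value of the
# target coefficient to the profile (penalized) log-likelihood, or NA on
# failure; counts evaluations against the budget.
pl_bound <- function(prof, est, wald_bound, loglik_max, level, max_eval) {
  target <- stats::qchisq(level, 1)
  evals <- 0L
  f <- function(b) {
    evals <<- evals + 1L
    lp <- prof(b)
    if (!is.finite(lp)) return(NA_real_)
    2 * (loglik_max - lp) - target
  }
  dir <- sign(wald_bound - est)
  if (dir == 0) dir <- 1
  halfw <- abs(wald_bound - est)
  if (!is.finite(halfw) || halfw == 0) halfw <- 0.5
  # expand geometrically until the profile deviance exceeds the cutoff
  lo <- est
  flo <- -target   # deviance 0 at the maximum
  hi <- NA_real_
  fhi <- NA_real_
  mult <- 1
  while (evals < max_eval) {
    cand <- est + dir * mult * halfw
    fc <- f(cand)
    if (is.na(fc)) { mult <- mult * 0.7 + 0.3; next }
    if (fc > 0) { hi <- cand; fhi <- fc; break }
    lo <- cand; flo <- fc
    mult <- mult * 2
    if (mult > 1e4) break
  }
  if (is.na(hi) || evals >= max_eval)
    return(c(bound = est + dir * mult * halfw, conv = 0))
  root <- tryCatch(
    stats::uniroot(f, lower = min(lo, hi), upper = max(lo, hi),
                   f.lower = if (lo <= hi) flo else fhi,
                   f.upper = if (lo <= hi) fhi else flo, tol = 1e-6,
                   maxiter = max(10L, max_eval - evals))$root,
    error = function(e) NA_real_)
  if (is.na(root)) c(bound = hi, conv = 0) else c(bound = root, conv = 1)
}

#' @export
profile_ci.firth_logit <- function(object, name, level = 0.95,
                                   max_eval = 200L) {
  k <- match(name, names(object$coefficients))
  if (is.na(k)) stop("unknown coefficient: ", name, call. = FALSE)
  est <- object$coefficients[k]
  start <- object$coefficients
  prof <- function(b) {
    fit <- logit_core(object$X, object$y, object$offset,
                      firth = object$firth, fixed = k, at = b,
                      start = start, max_iter = object$max_iter,
                      tol = object$tol)
    if (!fit$converged) return(NA_real_)
    start <<- fit$beta   # warm start for nearby evaluations
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
lr_test.firth_logit <- function(object, name) {
  k <- match(name, names(object$coefficients))
  if (is.na(k)) stop("unknown coefficient: ", name, call. = FALSE)
  fit0 <- logit_core(object$X, object$y, object$offset,
                     firth = object$firth, fixed = k, at = 0,
                     start = object$coefficients,
                     max_iter = object$max_iter, tol = object$tol)
  if (!fit0$converged) return(NA_real_)
  dev <- max(0, 2 * (object$loglik - fit0$loglik))
  stats::pchisq(dev, df = 1, lower.tail = FALSE)
}
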
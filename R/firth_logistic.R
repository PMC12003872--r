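#' Logistic regression with offset and optional Firth penalization
#'
#' Fits `logit P(y = 1) = offset + X %*% gamma` by Fisher scoring. With
#' `firth = TRUE` the Jeffreys-prior penalized likelihood
#' `l(gamma) + 0.5 * log det I(gamma)` is maximized via Firth's modified
#' score `U*(gamma) = X' (y - pi + h (1/2 - pi))`, where `h` are the
#' diagonal elements of the weighted hat matrix. The penalization removes
#' the leading small-sample bias of the ML estimate and keeps estimates
#' finite under complete or quasi-complete separation. Step-halving is
#' applied whenever a Newton step would decrease the (penalized)
#' log-likelihood.
#'
#' Standard errors come from the inverse Fisher information at the
#' optimum; Wald intervals are `estimate +/- z * se`. Profile-likelihood
#' intervals and tests are available through [profile_ci()] and
#' [lr_test()], and are computed up front when `pl = TRUE`.
#'
#' @param X design matrix (full column rank, named columns).
#' @param y binary response vector (0/1).
#' @param offset per-observation fixed offset added to the linear
#'   predictor; defaults to zero.
#' @param firth logical; apply Firth's bias-eliminating penalization.
#' @param pl logical; also compute profile-likelihood intervals and
#'   penalized-LR p-values for every coefficient.
#' @param level confidence level for intervals.
#' @param max_iter maximum Fisher-scoring iterations.
#' @param tol convergence tolerance on the max-norm of the (modified)
#'   score.
#' @return An object of class `firth_logit`: list with elements
#'   `coefficients`, `se`, `vcov`, `loglik` (penalized when `firth`),
#'   `converged`, `iterations`, `wald_ci`, `pl_ci` (with per-bound
#'   convergence flags), `p_wald`, `p_pl`, plus the fit ingredients
#'   needed for profiling.
#' @examples
#' co <- build_case_only(generate_cohort(scenario_config(n = 400), seed = 2))
#' f <- fit_logistic(cbind(`(Intercept)` = 1, M = co$M), co$T,
#'                   offset = co$offset, firth = TRUE)
#' coef(f)
#' @export
fit_logistic <- function(X, y, offset = rep(0, length(y)), firth = TRUE,
                         pl = TRUE, level = 0.95,
                         max_iter = 1000L, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)),
            length(offset) == nrow(X), all(is.finite(offset)))
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)

  fit <- logit_core(X, y, offset, firth = firth, fixed = integer(0),
                    at = numeric(0), start = rep(0, ncol(X)),
                    max_iter = max_iter, tol = tol)
  p <- ncol(X)
  se <- sqrt(diag(fit$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  wald_ci <- cbind(lower = fit$beta - z * se, upper = fit$beta + z * se)
  rownames(wald_ci) <- colnames(X)
  p_wald <- 2 * stats::pnorm(-abs(fit$beta / se))

  out <- list(coefficients = stats::setNames(fit$beta, colnames(X)),
              se = stats::setNames(se, colnames(X)), vcov = fit$vcov,
              loglik = fit$loglik, converged = fit$converged,
              iterations = fit$iterations,
              wald_ci = wald_ci, pl_ci = NULL,
              p_wald = stats::setNames(p_wald, colnames(X)), p_pl = NULL,
              firth = firth, level = level, X = X, y = y, offset = offset,
              max_iter = max_iter, tol = tol)
  class(out) <- "firth_logit"
  if (pl && fit$converged) {
    out$pl_ci <- do.call(rbind, lapply(colnames(X), function(nm)
      profile_ci(out, nm, level = level)))
    rownames(out$pl_ci) <- colnames(X)
    out$p_pl <- vapply(colnames(X), function(nm) lr_test(out, nm), 0)
  }
  out
}

#' @export
coef.firth_logit <- function(object, ...) object$coefficients

#' @export
vcov.firth_logit <- function(object, ...) object$vcov

#' @export
logLik.firth_logit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
print.firth_logit <- function(x, ...) {
  cat(sprintf("%s logistic regression with offset\n",
              if (x$firth) "Firth-penalized" else "Maximum-likelihood"))
  tab <- cbind(coef = x$coefficients, se = x$se,
               `wald lo` = x$wald_ci[, 1], `wald hi` = x$wald_ci[, 2])
  if (!is.null(x$pl_ci))
    tab <- cbind(tab, `pl lo` = x$pl_ci[, "lower"],
                 `pl hi` = x$pl_ci[, "upper"])
  print(round(tab, 4))
  cat(sprintf("loglik%s = %.4f, converged = %s (%d iterations)\n",
              if (x$firth) " (penalized)" else "", x$loglik,
              x$converged, x$iterations))
  invisible(x)
}

# Core (possibly constrained) Fisher scoring for the offset logistic
# model. `fixed` gives indices of coefficients held at `at`; the free
# coefficients maximize the same (penalized) likelihood, giving the
# profile value used by profile_ci / lr_test.
logit_core <- function(X, y, offset, firth, fixed, at, start,
                       max_iter = 1000L, tol = 1e-8) {
  p <- ncol(X)
  free <- setdiff(seq_len(p), fixed)
  beta <- start
  beta[fixed] <- at

  penloglik <- function(beta) {
    eta <- offset + drop(X %*% beta)
    ll <- sum(y * eta - log1p(exp(pmin(eta, 500))))
    if (firth) {
      pi <- stats::plogis(eta)
      w <- pmax(pi * (1 - pi), 1e-300)
      ll <- ll + 0.5 * determinant(crossprod(X, w * X))$modulus[1]
    }
    ll
  }

  ll <- penloglik(beta)
  converged <- length(free) == 0L  # fully constrained: nothing to optimize
  iter <- 0L
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    eta <- offset + drop(X %*% beta)
    pi <- stats::plogis(eta)
    w <- pi * (1 - pi)
    info <- crossprod(X, w * X)
    resid <- y - pi
    if (firth) {
      XW <- X * sqrt(pmax(w, 0))
      h <- rowSums((XW %*% tryCatch(solve(info), error = function(e)
        pinv_sym(info))) * XW)
      resid <- resid + h * (0.5 - pi)
    }
    score <- drop(crossprod(X, resid))
    if (max(abs(score[free])) < tol) { converged <- TRUE; break }
    delta <- rep(0, p)
    sub <- tryCatch(solve(info[free, free, drop = FALSE], score[free]),
                    error = function(e) NULL)
    if (is.null(sub)) break
    delta[free] <- sub
    # step-halving: retreat while the (penalized) objective worsens
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- penloglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-10) break
      step <- step / 2
      if (step < 1e-10) { cand <- beta; ll_new <- ll; break }
    }
    if (max(abs(cand - beta)) < 1e-12 && !firth) break
    beta <- cand
    ll <- ll_new
  }
  eta <- offset + drop(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  info <- crossprod(X, w * X)
  vc <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, p, p))
  list(beta = beta, loglik = penloglik(beta), vcov = vc,
       converged = converged && (iter < max_iter || max_iter == 0L),
       iterations = iter)
}

# Moore-Penrose pseudo-inverse fallback used only when the information matrix is
# numerically singular mid-iteration.
pinv_sym <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
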
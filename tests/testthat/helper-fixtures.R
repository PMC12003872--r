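# Fixture builders shared across tests. Everything is generated in code;
# no data files.

# Six-subject cohort with hand-countable risk sets: events at times 1, 2
# and 3; the two 5-year survivors are administratively censored.
fixture_cohort6 <- function() {
  as_cohort(data.frame(
    id = 1:6,
    M = c(0, 1, 0, 1, 0, 1),
    T = c(1, 0, 1, 0, 1, 0),
    time = c(1, 2, 3, 4, 5, 5),
    event = c(1, 1, 1, 0, 0, 0)))
}

# Small random cohort for consistency properties.
fixture_cohort <- function(n = 300, seed = 1, ...) {
  generate_cohort(scenario_config(n = n, seed = seed, ...), seed = seed)
}

# Independent penalized binomial log-likelihood for intercept-only data,
# used as the 1-D oracle for the Firth logistic fit: l*(b) =
# y*b - n*log(1+e^b) + 0.5*log(n * pi * (1 - pi)).
penll_intercept <- function(b, y, n) {
  pi <- plogis(b)
  y * b - n * log1p(exp(b)) + 0.5 * log(n * pi * (1 - pi))
}

# Independent penalized Cox partial log-likelihood computed by direct
# summation (Breslow), used as the grid-search oracle on tiny fixtures.
penll_cox_direct <- function(beta, X, time, event, firth = TRUE) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ev <- which(event == 1)
  ll <- 0
  info <- matrix(0, ncol(X), ncol(X))
  for (i in ev) {
    at_risk <- which(time >= time[i])
    s0 <- sum(w[at_risk])
    s1 <- colSums(w[at_risk] * X[at_risk, , drop = FALSE])
    ll <- ll + eta[i] - log(s0)
    s2 <- t(X[at_risk, , drop = FALSE]) %*%
      (w[at_risk] * X[at_risk, , drop = FALSE])
    info <- info + s2 / s0 - tcrossprod(s1 / s0)
  }
  if (firth) {
    d <- determinant(info)
    if (d$sign <= 0) return(-Inf)
    ll <- ll + 0.5 * d$modulus[1]
  }
  ll
}

# Successive-refinement grid maximization of a scalar-argument-vector
# objective over [-5, 5]^p; an enumeration oracle independent of any
# Newton machinery in the package.
grid_maximize <- function(f, p, lower = -5, upper = 5, levels = 7) {
  center <- rep(0, p)
  width <- (upper - lower) / 2
  for (l in seq_len(levels)) {
    axes <- lapply(seq_len(p), function(j)
      seq(center[j] - width, center[j] + width, length.out = 11))
    pts <- as.matrix(do.call(expand.grid, axes))
    vals <- apply(pts, 1, f)
    center <- pts[which.max(vals), ]
    width <- width / 4
  }
  center
}
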
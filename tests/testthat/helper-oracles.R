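# Independent oracles used across the suite.  Everything here is written
# from the model definitions directly (quadrature, enumeration, hand
# formulas), not by calling the package's samplers.

# mixing density written out independently of nid_mixing_density()
oracle_mixing_density <- function(u, family, shape) {
  switch(family,
    t = stats::dgamma(u, shape / 2, rate = shape / 2),
    slash = ifelse(u > 0 & u < 1, shape * u^(shape - 1), 0),
    laplace = shape * u^(-2) * exp(-shape / u),
    stop("no continuous mixing density for ", family))
}

# cdf of the conditional latent-scale kernel
#   p(u | e, tau) propto sqrt(u) exp(-u tau e^2 / 2) g(u; shape)
# by dense-grid quadrature (trapezoid over 2e4 points, linear interpolation
# between them); `hi` must cover the draws being tested.
oracle_scale_cdf <- function(q, e, tau, family, shape) {
  f <- function(u) sqrt(u) * exp(-u * tau * e^2 / 2) *
    oracle_mixing_density(u, family, shape)
  # dense trapezoid grid over the body, adaptive quadrature for the tail
  m <- if (family == "slash") 1 else 20
  grid <- seq(0, m, length.out = 1e5 + 1)
  fv <- f(grid); fv[1] <- 0
  h <- grid[2] - grid[1]
  cum <- c(0, cumsum((fv[-1] + fv[-length(fv)]) / 2 * h))
  tail_mass <- if (family == "slash") 0 else
    stats::integrate(f, m, Inf, rel.tol = 1e-9)$value
  Z <- cum[length(cum)] + tail_mass
  body_cdf <- stats::approxfun(grid, cum / Z, yleft = 0)
  out <- numeric(length(q))
  inb <- q <= m
  out[inb] <- body_cdf(q[inb])
  for (i in which(!inb))
    out[i] <- (cum[length(cum)] +
                 stats::integrate(f, m, q[i], rel.tol = 1e-9)$value) / Z
  out
}

# two-group marginal pattern probabilities for a single gene by brute-force
# quadrature over the block means (the collapsed update's target)
oracle_pattern_probs_2group <- function(y, grp, u, tau_eps, tau_mu, p) {
  lik <- function(m, idx) vapply(m, function(mm)
    prod(stats::dnorm(y[idx], mm, 1 / sqrt(tau_eps * u[idx]))), numeric(1))
  marg <- function(idx, tm) stats::integrate(function(m)
    lik(m, idx) * stats::dnorm(m, 0, 1 / sqrt(tm)),
    -40, 40, rel.tol = 1e-12)$value
  m_eq <- marg(seq_along(y), tau_mu[1])
  m_de <- marg(which(grp == 1), tau_mu[2]) * marg(which(grp == 2), tau_mu[3])
  w <- c(p[1] * m_eq, p[2] * m_de)
  w / sum(w)
}

# set partitions of 1..k by canonicalized exhaustive assignment search --
# deliberately a different algorithm from the package's restricted-growth
# recursion
oracle_partitions <- function(k) {
  grids <- do.call(expand.grid, rep(list(seq_len(k)), k))
  canon <- apply(grids, 1, function(a) {
    relab <- integer(k); nxt <- 0L
    for (i in seq_len(k)) {
      if (relab[a[i]] == 0L) { nxt <- nxt + 1L; relab[a[i]] <- nxt }
    }
    paste(relab[a], collapse = "")
  })
  unique(canon)
}

# Bayesian decision rates evaluated longhand from their definitions
oracle_rates <- function(pi, kappa) {
  r <- as.numeric(pi > kappa)
  list(bFPR = sum((1 - pi) * r) / sum(1 - pi),
       bTPR = sum(pi * r) / sum(pi),
       bFDR = if (sum(r) == 0) 0 else sum((1 - pi) * r) / sum(r))
}

# AUC by explicit pair counting (concordant pairs + half ties)
oracle_auc <- function(score, truth) {
  pos <- score[truth == 1]; neg <- score[truth == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# small deterministic two-group dataset builder
toy_dataset <- function(N = 10, n1 = 4, n2 = 4, seed = 42, delta = rep(0, N),
                        base = 0, sd = 1) {
  set.seed(seed)
  y <- matrix(rnorm(N * (n1 + n2), base, sd), N, n1 + n2)
  y[, seq_len(n1)] <- y[, seq_len(n1)] + delta
  expression_dataset(y, rep(c("g1", "g2"), c(n1, n2)))
}
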
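test_that("Gelman-Rubin statistic matches hand evaluation", {
  # two stationary chains from one normal stream
  set.seed(1)
  tr <- cbind(rnorm(5000), rnorm(5000))
  r <- gelman_rubin(tr)
  expect_gt(r, 0.99); expect_lt(r, 1.05)
  # direct hand evaluation: W = 5/3, B = 20000
  expect_equal(gelman_rubin(cbind(1:4, 101:104)),
               sqrt((3 / 4 * 5 / 3 + 20000 / 4) / (5 / 3)),
               tolerance = 1e-12)
  expect_equal(round(gelman_rubin(cbind(1:4, 101:104)), 2), 54.78)
  expect_error(gelman_rubin(cbind(rep(2, 10), rep(2, 10))), "undefined")
  expect_error(gelman_rubin(matrix(1:4, 4, 1)), "two chains")
})

test_that("chain initialization is deterministic and as documented", {
  d <- toy_dataset(N = 6, seed = 3)
  pats <- enumerate_partitions(2)
  s1 <- nidge:::init_state(d, "normal", pats, chain = 1L)
  expect_true(all(s1$u == 1))
  expect_true(all(s1$z == 0L))
  expect_equal(s1$p, c(0.5, 0.5))
  # chain 1 means are the group sample means; later chains only jitter
  gm <- cbind(rowMeans(d$values[, 1:4]), rowMeans(d$values[, 5:8]))
  expect_equal(s1$mu, gm)
  set.seed(99)
  s2 <- nidge:::init_state(d, "normal", pats, chain = 2L)
  expect_false(any(s2$mu == gm))
  expect_lt(max(abs(s2$mu - gm)), 1)
  # degenerate zero-variance gene: precision floored at the cap
  dd <- d
  dd$values[2, ] <- 5
  s3 <- nidge:::init_state(dd, "normal", pats)
  expect_equal(s3$tau_eps[2], 1e8)
  # family shape containers at their defaults
  expect_equal(nidge:::init_state(d, "t", pats)$nu[1, 1], 5)
  expect_equal(nidge:::init_state(d, "cn", pats)$nu[1, ], c(0.5, 0.5))
})

test_that("runs are exactly reproducible from the seed", {
  d <- toy_dataset(N = 8, seed = 4, delta = c(rep(2, 2), rep(0, 6)))
  cfg <- mcmc_config(n_iter = 400, n_burnin = 200, n_chains = 2, seed = 11)
  f1 <- run_chains(d, nid_family("cn", c(0.1, 0.25)), cfg)
  f2 <- run_chains(d, nid_family("cn", c(0.1, 0.25)), cfg)
  expect_identical(f1$pattern_counts, f2$pattern_counts)
  expect_identical(f1$chains[[1]]$p_trace, f2$chains[[1]]$p_trace)
  expect_identical(f1$pair_mean_diff, f2$pair_mean_diff)
})

test_that("collapsed pattern update matches the quadrature oracle", {
  y <- matrix(c(1.2, 0.4, 0.9, -0.3, -1.1, 0.2), 1, 6)
  grp <- rep(1:2, each = 3)
  u <- matrix(c(1, 0.3, 2, 1, 0.5, 1.4), 1, 6)
  tau_eps <- 0.8; tau_mu <- c(0.4, 0.25, 0.6); p <- c(0.7, 0.3)
  tabs <- nidge:::pattern_tables(enumerate_partitions(2), 2)
  got <- nidge:::.cpp_pattern_probs(y, grp - 1L, tabs$block_of, tabs$prec_of,
                                    tabs$nblocks, u, tau_eps, tau_mu, p)
  want <- oracle_pattern_probs_2group(y[1, ], grp, u[1, ], tau_eps, tau_mu, p)
  expect_equal(as.numeric(got), want, tolerance = 1e-8)

  # conjugate mean draw under a forced DE pattern matches closed form
  st <- list(mu = matrix(0, 1, 2), u = u, tau_eps = tau_eps,
             nu = matrix(1, 1, 2), z = 0L, p = c(1e-14, 1 - 1e-14),
             tau_mu = tau_mu)
  set.seed(5)
  dr <- nidge:::.cpp_pattern_mean_draws(y, grp - 1L, tabs$block_of,
                                        tabs$prec_of, tabs$nblocks, st, 4e4)
  expect_true(all(dr$z == 2L))
  A <- tau_eps * sum(u[1, 1:3]); C <- tau_eps * sum(u[1, 1:3] * y[1, 1:3])
  pp <- tau_mu[2] + A
  expect_equal(mean(dr$mu[, 1]), C / pp, tolerance = 4 / sqrt(4e4))
  expect_equal(sd(dr$mu[, 1]), 1 / sqrt(pp), tolerance = 0.03)
  # degenerate mixing weight pins the pattern at the null
  st$p <- c(1 - 1e-14, 1e-14)
  dr0 <- nidge:::.cpp_pattern_mean_draws(y, grp - 1L, tabs$block_of,
                                         tabs$prec_of, tabs$nblocks, st, 200)
  expect_true(all(dr0$z == 1L))
})

test_that("t degrees-of-freedom Metropolis matches its quadrature target", {
  # fixed latent scales; long MH chain against the normalized conditional
  u <- c(0.8, 1.3, 0.5, 1.1, 0.9, 1.6)
  n <- length(u); slu <- sum(log(u)); su <- sum(u)
  logcond <- function(v) n * (v / 2 * log(v / 2) - lgamma(v / 2)) +
    (v / 2) * slu - (v / 2) * su
  Z <- integrate(function(v) exp(logcond(v)), 0, 100, rel.tol = 1e-10)$value
  cdf <- function(q) vapply(q, function(x)
    integrate(function(v) exp(logcond(v)), 0, min(x, 100),
              rel.tol = 1e-10)$value / Z, numeric(1))
  set.seed(6)
  tr <- nidge:::.cpp_t_df_mh(2, n, slu, su, 2e5, 100)
  tr <- tr[seq(1000, length(tr), by = 20)]
  ks <- suppressWarnings(ks.test(tr, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("posterior DE probability is invariant to gene order and label swap", {
  delta <- c(rep(1.5, 3), rep(0, 9))
  d <- toy_dataset(N = 12, seed = 8, delta = delta)
  cfg <- mcmc_config(n_iter = 6000, n_burnin = 1000, n_chains = 1, seed = 2)
  pi1 <- de_probability(run_chains(d, nid_family("normal"), cfg))$pi
  # reorder genes: probabilities travel with the genes (within MC error)
  perm <- c(4:12, 1:3)
  d2 <- expression_dataset(d$values[perm, ], rep(c("g1", "g2"), c(4, 4)))
  pi2 <- de_probability(run_chains(d2, nid_family("normal"), cfg))$pi
  expect_lt(mean(abs(pi2 - pi1[perm])), 0.04)
  expect_lt(max(abs(pi2 - pi1[perm])), 0.12)
  # swapping group labels with mirrored columns leaves probabilities alone
  d3 <- expression_dataset(d$values[, c(5:8, 1:4)],
                           rep(c("g2", "g1"), c(4, 4)))
  pi3 <- de_probability(run_chains(d3, nid_family("normal"), cfg))$pi
  expect_lt(mean(abs(pi3 - pi1)), 0.04)
  expect_lt(max(abs(pi3 - pi1)), 0.12)
})

test_that("normal-family posterior ranking tracks t-statistic evidence", {
  # the posterior DE probability is not a monotone function of |t| (the
  # learned slab scale shrinks genes adaptively and strong genes saturate
  # at 1), but the two orderings must agree strongly
  set.seed(10)
  N <- 200; nn <- 6
  delta <- runif(N, 0, 1.5) * sample(c(-1, 1), N, TRUE)
  d <- toy_dataset(N = N, n1 = nn, n2 = nn, seed = 10, delta = delta)
  cfg <- mcmc_config(n_iter = 6000, n_burnin = 1000, n_chains = 1, seed = 3)
  post <- de_probability(run_chains(d, nid_family("normal"), cfg))
  tstat <- apply(d$values, 1, function(y)
    abs(t.test(y[1:nn], y[-(1:nn)], var.equal = TRUE)$statistic))
  expect_gt(cor(rank(post$pi), rank(tstat), method = "spearman"), 0.7)
  # the strongest posterior calls are strong t-statistics as well
  top <- order(-post$pi)[1:30]
  expect_gte(mean(rank(tstat)[top] > N / 2), 0.9)
})

test_that("convergence diagnostics flag divergent chains, not stationary ones", {
  d <- toy_dataset(N = 10, seed = 12, delta = c(rep(2, 2), rep(0, 8)))
  cfg <- mcmc_config(n_iter = 2000, n_burnin = 1000, n_chains = 2, seed = 5)
  fit <- run_chains(d, nid_family("normal"), cfg)
  expect_false(is.null(fit$rhat))
  expect_true(all(is.finite(fit$rhat)))
  expect_lt(fit$rhat[["p_DE"]], 1.2)
})
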
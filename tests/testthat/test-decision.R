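test_that("Bayesian decision rates match hand evaluation exactly", {
  b <- bayes_rates(c(0.9, 0.8, 0.3, 0.1), 0.5)
  expect_equal(b$calls, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(b$bFDR, 0.15)
  expect_equal(b$bFPR, 0.3 / 1.9)
  expect_equal(b$bTPR, 1.7 / 2.1)
  expect_equal(b$bTNR, 1 - b$bFPR)
  expect_equal(b$bFNR, 1 - b$bTPR)
  # certainty on every gene: no false discoveries below threshold 1
  b1 <- bayes_rates(rep(1, 5), 0.8)
  expect_equal(b1$bFDR, 0); expect_equal(b1$bTPR, 1)
  # kappa = 1 calls nothing: flagged-zero bFDR, zero bTPR
  b2 <- bayes_rates(c(0.9, 0.8), 1)
  expect_equal(b2$n_called, 0L)
  expect_true(b2$no_calls)
  expect_equal(b2$bFDR, 0); expect_equal(b2$bTPR, 0)
})

test_that("rates agree with the longhand oracle on random probability sets", {
  set.seed(1)
  for (r in 1:20) {
    pi <- runif(sample(3:40, 1))
    kappa <- runif(1)
    b <- bayes_rates(pi, kappa)
    o <- oracle_rates(pi, kappa)
    expect_equal(b$bFPR, o$bFPR)
    expect_equal(b$bTPR, o$bTPR)
    expect_equal(b$bFDR, o$bFDR)
  }
})

test_that("call count and bFDR shrink as the threshold rises", {
  set.seed(2)
  pi <- runif(50)
  grid <- seq(0, 1, by = 0.05)
  reports <- lapply(grid, function(k) bayes_rates(pi, k))
  ncalls <- vapply(reports, `[[`, 0L, "n_called")
  expect_true(all(diff(ncalls) <= 0))
  bfdr <- vapply(reports, `[[`, 0, "bFDR")
  called <- ncalls > 0
  expect_true(all(diff(bfdr[called]) <= 1e-12))
  # bFDR never exceeds the largest posterior-null probability among calls
  for (b in reports[called])
    expect_lte(b$bFDR, max(1 - pi[b$calls]) + 1e-12)
})

test_that("posterior-weighted ROC has the documented geometry", {
  # near-certain probabilities: hand trapezoid over the 6-point grid gives
  # 0.9875 (the posterior weighting leaves a little residual uncertainty)
  r <- roc_auc(c(0.99, 0.98, 0.01, 0.02))
  expect_gt(r$auc, 0.98)
  expect_equal(r$auc, 0.9875)
  expect_equal(r$points$bFPR[1], 0); expect_equal(r$points$bTPR[1], 0)
  n <- nrow(r$points)
  expect_equal(r$points$bFPR[n], 1); expect_equal(r$points$bTPR[n], 1)
  expect_true(all(diff(r$points$bFPR) >= 0))
  expect_true(all(diff(r$points$bTPR) >= 0))
  # flat probabilities: flagged degenerate, AUC 1/2
  rd <- roc_auc(rep(0.5, 6))
  expect_true(rd$degenerate)
  expect_equal(rd$auc, 0.5)
  # hand evaluation on the 6-point grid for pi = (0.9, 0.3, 0.8, 0.1)
  pi <- c(0.9, 0.3, 0.8, 0.1)
  grid <- sort(unique(c(0, pi, 1)), decreasing = TRUE)
  pts <- t(vapply(grid, function(k) {
    o <- oracle_rates(pi, k); c(o$bFPR, o$bTPR)
  }, numeric(2)))
  hand_auc <- sum(diff(pts[, 1]) * (utils::head(pts[, 2], -1) +
                                      utils::tail(pts[, 2], -1)) / 2)
  expect_equal(roc_auc(pi)$auc, hand_auc)
})

test_that("truth-based AUC is the Mann-Whitney statistic with tie credit", {
  expect_equal(truth_roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(truth_roc_auc(c(0.9, 0.3, 0.8, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(truth_roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(truth_roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
  set.seed(3)
  for (r in 1:10) {
    sc <- round(runif(30), 2)  # induce some ties
    tr <- rbinom(30, 1, 0.4)
    if (length(unique(tr)) < 2) next
    expect_equal(truth_roc_auc(sc, tr), oracle_auc(sc, tr))
  }
})

test_that("posterior-weighted ROC agrees with truth ROC at posterior extremes", {
  pi <- c(rep(1, 4), rep(0, 6))
  expect_equal(roc_auc(pi)$auc, truth_roc_auc(pi, pi))
})

test_that("posterior summaries pool chains and expose pairwise structure", {
  d <- toy_dataset(N = 8, seed = 5, delta = c(rep(4, 2), rep(0, 6)))
  cfg <- mcmc_config(n_iter = 1500, n_burnin = 500, n_chains = 2, seed = 7)
  fit <- run_chains(d, nid_family("normal"), cfg)
  post <- de_probability(fit)
  expect_length(post$pi, 8)
  expect_true(all(post$pi >= 0 & post$pi <= 1))
  # two groups: the single pairwise probability is the global one
  expect_equal(unname(post$pairwise[, 1]), post$pi)
  expect_equal(rowSums(post$pattern_prob), rep(1, 8))
  # pooling identity: global pi is the average of the per-chain frequencies
  per_chain <- sapply(fit$chains, function(ch)
    1 - ch$pattern_counts[, 1] / ch$n_keep)
  expect_equal(post$pi, rowMeans(per_chain))
  # shifted genes separate from nulls
  expect_gt(min(post$pi[1:2]), max(post$pi[3:8]))
})

test_that("three-group fits report union-intersection probabilities", {
  set.seed(6)
  N <- 12
  y <- matrix(rnorm(N * 12), N, 12)
  y[1:2, 9:12] <- y[1:2, 9:12] + 4  # group C differs for genes 1-2
  d <- expression_dataset(y, rep(c("A", "B", "C"), each = 4))
  cfg <- mcmc_config(n_iter = 2000, n_burnin = 500, n_chains = 1, seed = 9)
  post <- de_probability(run_chains(d, nid_family("normal"), cfg))
  expect_equal(colnames(post$pairwise), c("A_vs_B", "A_vs_C", "B_vs_C"))
  # global probability dominates each pairwise probability
  for (q in 1:3) expect_true(all(post$pi >= post$pairwise[, q] - 1e-12))
  # the signal genes separate C from A and B much more than A from B
  expect_gt(min(post$pairwise[1:2, "A_vs_C"]), 0.8)
  expect_gt(min(post$pairwise[1:2, "B_vs_C"]), 0.8)
  expect_lt(max(post$pairwise[1:2, "A_vs_B"]),
            min(post$pairwise[1:2, "A_vs_C"]))
  # mixture over the five patterns sums to one
  expect_equal(sum(post$pattern_mix), 1, tolerance = 1e-12)
})
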
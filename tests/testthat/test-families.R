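test_that("family constructor validates shapes", {
  expect_s3_class(nid_family("t", 4), "nid_family")
  expect_error(nid_family("t", -1), "degrees of freedom")
  expect_error(nid_family("cn", c(0.5, 1.2)), "lambda, gamma")
  expect_error(nid_family("normal", 3), "no shape")
  expect_error(nid_family("slash", c(1, 2)), "exponent")
  # defaults fill in when no shape is given
  expect_equal(nid_family("cn")$shape, c(0.5, 0.5))
})

test_that("mixing densities match their stated forms and normalize", {
  # Beta(1, 1) mixing is uniform on (0, 1)
  expect_equal(nid_mixing_density(0.5, nid_family("slash", 1)), 1.0)
  # contaminated normal: two-point mass
  cn <- nid_family("cn", c(0.1, 0.25))
  expect_equal(nid_mixing_density(0.25, cn), 0.1)
  expect_equal(nid_mixing_density(1, cn), 0.9)
  expect_equal(nid_mixing_density(0.7, cn), 0)
  # t mixing at v = 4 is Gamma(2, rate 2)
  expect_equal(nid_mixing_density(1, nid_family("t", 4)),
               oracle_mixing_density(1, "t", 4))
  expect_error(nid_mixing_density(-1, cn), "positive")
  # continuous mixing laws integrate to 1
  for (fam in list(nid_family("t", 3), nid_family("slash", 2),
                   nid_family("laplace", 1.5))) {
    z <- integrate(function(u) nid_mixing_density(u, fam), 0, Inf,
                   rel.tol = 1e-9)$value
    expect_equal(z, 1, tolerance = 1e-6)
  }
})

test_that("marginal density has the stated closed forms", {
  expect_equal(dnid(0, 0, 1, nid_family("normal")), 1 / sqrt(2 * pi))
  cn <- nid_family("cn", c(0.1, 0.25))
  expect_equal(dnid(0, 0, 1, cn),
               0.1 * dnorm(0, 0, 2) + 0.9 * dnorm(0, 0, 1))
  # slash against brute-force quadrature of the mixture integral
  direct <- integrate(function(u) dnorm(1, 0, 1 / sqrt(u)) * 2 * u, 0, 1,
                      rel.tol = 1e-10)$value
  expect_equal(dnid(1, 0, 1, nid_family("slash", 2)), direct,
               tolerance = 1e-7)
  # t member is the scaled Student density
  expect_equal(dnid(1.3, 0.5, 2, nid_family("t", 3)),
               dt((1.3 - 0.5) / sqrt(2), 3) / sqrt(2))
})

test_that("marginal densities integrate to one for all families and shapes", {
  specs <- list(
    nid_family("normal"),
    nid_family("t", 1), nid_family("t", 4), nid_family("t", 30),
    nid_family("slash", 0.8), nid_family("slash", 2), nid_family("slash", 10),
    nid_family("cn", c(0.1, 0.1)), nid_family("cn", c(0.3, 0.5)),
    nid_family("cn", c(0.05, 0.9)),
    nid_family("laplace", 0.5), nid_family("laplace", 1),
    nid_family("laplace", 4))
  mu <- 2; sigma <- 1.7
  for (spec in specs) {
    # infinite limits: the heaviest members (Cauchy-like t, small slash
    # exponents) hold visible mass beyond any +-50 sd window
    z <- integrate(function(y) dnid(y, mu, sigma, spec), -Inf, Inf,
                   rel.tol = 1e-9, subdivisions = 400L)$value
    expect_equal(z, 1, tolerance = 1e-6,
                 label = paste("normalization of", spec$family))
  }
})

test_that("non-normal members are heavier-tailed than the normal", {
  mu <- 0; sigma <- 1; y <- mu + 10 * sqrt(sigma)
  for (spec in list(nid_family("t", 5), nid_family("slash", 2),
                    nid_family("cn", c(0.1, 0.25)), nid_family("laplace", 1)))
    expect_gt(dnid(y, mu, sigma, spec) / dnorm(y, mu, sqrt(sigma)), 1)
})

test_that("t with enormous df collapses to the normal density", {
  y <- seq(-5, 5, length.out = 201)
  expect_lt(max(abs(dnid(y, 0, 1, nid_family("t", 1e4)) - dnorm(y))), 1e-4)
})

test_that("sampler matches the marginal law", {
  set.seed(1)
  x <- rnid(1e5, 14, 1, nid_family("normal"))
  expect_lt(abs(mean(x) - 14), 3 / sqrt(1e5))
  set.seed(2)
  x <- rnid(1e5, 0, 1, nid_family("t", 2))
  ks <- suppressWarnings(ks.test(x, pt, df = 2))
  expect_gt(ks$p.value, 0.01)
  # contamination fraction of latent scale draws
  set.seed(3)
  u <- nidge:::rnid_mixing(1e5, nid_family("cn", c(0.1, 0.25)))
  expect_lt(abs(mean(u == 0.25) - 0.1), 3 * sqrt(0.1 * 0.9 / 1e5))
  # Laplace marginal: double exponential with scale sqrt(sigma/(2 v))
  set.seed(4)
  x <- rnid(1e5, 0, 2, nid_family("laplace", 1))
  b <- sqrt(2 / 2)
  ks <- suppressWarnings(
    ks.test(x, function(q) 0.5 + 0.5 * sign(q) * (1 - exp(-abs(q) / b))))
  expect_gt(ks$p.value, 0.01)
})

test_that("conditional scale draws follow the quadrature-normalized kernel", {
  # two independent batches per case; only a double rejection fails (an
  # exact sampler yields uniform KS p-values, so single-batch rejections
  # at any level are expected across a grid this size)
  set.seed(5)
  cases <- expand.grid(e = c(0.3, 1.5, 4), tau = c(0.5, 2))
  specs <- list(nid_family("t", 4), nid_family("slash", 2),
                nid_family("laplace", 1))
  for (spec in specs) for (r in seq_len(nrow(cases))) {
    e <- cases$e[r]; tau <- cases$tau[r]
    pv <- replicate(2, {
      draws <- r_scale_conditional(2e4, e, tau, spec)
      suppressWarnings(ks.test(draws, function(q)
        oracle_scale_cdf(q, e, tau, spec$family, spec$shape[1])))$p.value
    })
    expect_gt(max(pv), 0.01,
              label = sprintf("%s kernel at e=%g tau=%g", spec$family, e, tau))
  }
})

test_that("degenerate residuals still give valid conditional draws", {
  # t kernel at e = 0 collapses to Gamma((v+1)/2, v/2)
  set.seed(6)
  d <- r_scale_conditional(5e4, 0, 1, nid_family("t", 4))
  ks <- suppressWarnings(ks.test(d, pgamma, shape = 2.5, rate = 2))
  expect_gt(ks$p.value, 0.01)
  d <- r_scale_conditional(100, 0, 1, nid_family("laplace", 2))
  expect_true(all(d > 0))
})

test_that("contaminated-normal conditional weight matches hand evaluation", {
  # lambda sqrt(gamma) / (lambda sqrt(gamma) + 1 - lambda) at e = 0
  expect_equal(cn_scale_weight(0, 1, 0.1, 0.25), 1 / 19)
  set.seed(7)
  d <- r_scale_conditional(2e4, 0, 1, nid_family("cn", c(0.1, 0.25)))
  expect_lt(abs(mean(d == 0.25) - 1 / 19), 3 * sqrt((1 / 19) * (18 / 19) / 2e4))
  # large residual pushes the weight toward the contaminated point
  expect_gt(cn_scale_weight(6, 1, 0.1, 0.25), 0.9)
})
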
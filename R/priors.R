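#' Hyperprior configuration
#'
#' All precision parameters (per-gene error precisions and the prior
#' precisions of the block means) carry Gamma(shape, rate) priors with the
#' low-informative default Gamma(1, 0.005) (mean 200, i.e. prior standard
#' deviations around 0.07 on the expression scale, but with heavy spread).
#' The pattern mixing probabilities carry a symmetric Dirichlet prior with
#' unit concentration (uniform on the simplex; for two groups this is the
#' Beta(1, 1) prior on the proportion of differentially expressed genes).
#' Family shape priors: t degrees of freedom uniform(0, 100); slash
#' exponent Gamma(1, 0.005); contaminated-normal lambda and gamma
#' uniform(0, 1); Laplace rate Gamma(1, 0.005).
#'
#' @param prec_shape,prec_rate Gamma prior on every precision.
#' @param dirichlet_conc Concentration of the symmetric Dirichlet pattern
#'   prior.
#' @param t_df_max Upper end of the uniform prior on the t degrees of
#'   freedom.
#' @return A list of class `hyperprior_config`.
#' @export
hyperprior_config <- function(prec_shape = 1, prec_rate = 0.005,
                              dirichlet_conc = 1, t_df_max = 100) {
  stopifnot(prec_shape > 0, prec_rate > 0, dirichlet_conc > 0, t_df_max > 0)
  structure(list(prec_shape = prec_shape, prec_rate = prec_rate,
                 dirichlet_conc = dirichlet_conc, t_df_max = t_df_max),
            class = "hyperprior_config")
}

# packed form consumed by the C++ sweep
hyper_vec <- function(config) {
  c(config$prec_shape, config$prec_rate, config$t_df_max)
}

#' Draw from the prior predictive of the hierarchical model
#'
#' Samples one complete fake study from the model's prior: precision
#' hyperparameters from their Gamma priors, mixing probabilities from the
#' Dirichlet prior, per-gene equality patterns, block means from the
#' pattern-specific zero-mean normal priors (a block shared by several
#' groups uses the shared precision; a singleton block for group s uses the
#' group-s precision), per-gene error precisions and family shapes from
#' their priors, and finally observations through the scale-mixture
#' representation.  This is the generator used by joint-distribution
#' (Geweke-style) validation of the sampler.
#'
#' @param family Family name (as in [nid_family()]).
#' @param N Number of genes.
#' @param group_sizes Integer vector of per-group replicate counts.
#' @param config A [hyperprior_config()].
#' @return A list with `data` (an [expression_dataset()]), `patterns` (the
#'   pattern list), and `params` (z, mu, tau_eps, nu, p, tau_mu, u).
#' @export
prior_predictive_draw <- function(family, N, group_sizes,
                                  config = hyperprior_config()) {
  k <- length(group_sizes)
  patterns <- enumerate_partitions(k)
  P <- length(patterns)
  params <- prior_param_draw(family, N, k, patterns, config)
  dat <- data_given_params(params, family, N, group_sizes)
  list(data = dat$data, patterns = patterns,
       params = c(params, list(u = dat$u)))
}

# parameter-level prior draw (everything except u and y)
prior_param_draw <- function(family, N, k, patterns, config) {
  P <- length(patterns)
  p <- rgamma(P, config$dirichlet_conc, 1)
  p <- p / sum(p)
  tau_mu <- rgamma(k + 1, config$prec_shape, config$prec_rate)
  z <- sample.int(P, N, replace = TRUE, prob = p)
  mu <- matrix(0, N, k)
  for (i in seq_len(N)) {
    a <- patterns[[z[i]]]$assignment
    for (b in seq_len(max(a))) {
      members <- which(a == b)
      prec <- if (length(members) == 1L) tau_mu[members + 1L] else tau_mu[1L]
      mu[i, members] <- rnorm(1, 0, 1 / sqrt(prec))
    }
  }
  tau_eps <- rgamma(N, config$prec_shape, config$prec_rate)
  nu <- switch(family,
    normal = matrix(1, N, 2),
    t = cbind(runif(N, 0, config$t_df_max), 1),
    slash = cbind(rgamma(N, config$prec_shape, config$prec_rate), 1),
    cn = cbind(runif(N), runif(N)),
    laplace = cbind(rgamma(N, config$prec_shape, config$prec_rate), 1))
  list(z = z, mu = mu, tau_eps = tau_eps, nu = nu, p = p, tau_mu = tau_mu)
}

# observations (and latent scales) given drawn parameters
data_given_params <- function(params, family, N, group_sizes) {
  k <- length(group_sizes)
  grp <- rep(seq_len(k), group_sizes)
  n <- length(grp)
  u <- matrix(1, N, n)
  y <- matrix(0, N, n)
  for (i in seq_len(N)) {
    spec <- row_family(family, params$nu[i, ])
    ui <- rnid_mixing(n, spec)
    u[i, ] <- ui
    y[i, ] <- params$mu[i, grp] +
      rnorm(n, 0, 1 / sqrt(params$tau_eps[i] * ui))
  }
  list(data = expression_dataset(y, grp), u = u)
}

row_family <- function(family, nu_row) {
  switch(family,
    normal = nid_family("normal"),
    t = nid_family("t", nu_row[1]),
    slash = nid_family("slash", nu_row[1]),
    cn = nid_family("cn", nu_row[1:2]),
    laplace = nid_family("laplace", nu_row[1]))
}

#' Full-conditional parameters of a gene's error precision
#'
#' The conjugate update: with a Gamma(a, b) prior,
#' \eqn{\tau_\epsilon \mid \cdot \sim \Gamma(a + n/2,\;
#' b + \tfrac12 \sum u (y - \mu)^2)}.
#'
#' @param y Observations for one gene.
#' @param u Latent scale factors (same length).
#' @param mu Per-observation means.
#' @param config A [hyperprior_config()].
#' @return `list(shape, rate)` of the Gamma full conditional.
#' @export
tau_eps_conditional <- function(y, u, mu, config = hyperprior_config()) {
  stopifnot(length(y) == length(u))
  list(shape = config$prec_shape + length(y) / 2,
       rate = config$prec_rate + sum(u * (y - mu)^2) / 2)
}

#' Full-conditional Dirichlet parameters of the mixing probabilities
#'
#' @param pattern_counts Integer vector of genes currently assigned to each
#'   pattern.
#' @param config A [hyperprior_config()].
#' @return The Dirichlet parameter vector (concentration + counts).
#' @export
mixing_conditional <- function(pattern_counts, config = hyperprior_config()) {
  config$dirichlet_conc + pattern_counts
}

#' Full-conditional parameters of a family shape with a conjugate update
#'
#' Slash exponent: \eqn{\Gamma(a + n, b - \sum \log u)}; Laplace rate:
#' \eqn{\Gamma(a + n, b + \sum 1/u)}.
#'
#' @param u Latent scale factors for one gene.
#' @param family `"slash"` or `"laplace"`.
#' @param config A [hyperprior_config()].
#' @return `list(shape, rate)`.
#' @export
shape_conditional <- function(u, family = c("slash", "laplace"),
                              config = hyperprior_config()) {
  family <- match.arg(family)
  n <- length(u)
  rate <- switch(family,
    slash = config$prec_rate - sum(log(u)),
    laplace = config$prec_rate + sum(1 / u))
  list(shape = config$prec_shape + n, rate = rate)
}
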
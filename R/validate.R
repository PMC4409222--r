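#' Joint-distribution (Geweke-style) sampler check
#'
#' Successive-conditional simulation: starting from a draw of all
#' parameters from the prior, alternate (i) one Gibbs transition sweep of
#' the posterior sampler given the current data and (ii) an exact redraw of
#' the data given the current parameters and latent scales.  The chain's
#' stationary distribution is the model's joint prior, so the marginal
#' traces of any parameter must match its prior; comparing the traces of
#' the gene error precisions (Gamma prior) and the mixing probabilities
#' (Dirichlet prior) against their priors detects errors in any of the
#' full-conditional updates.
#'
#' @param family Family name (as in [nid_family()]).
#' @param N Genes.
#' @param group_sizes Per-group replicate counts.
#' @param n_sweeps Number of alternation steps.
#' @param thin Record every `thin`-th state (thinning reduces the
#'   autocorrelation that would distort distribution tests).
#' @param config A [hyperprior_config()].
#' @return A list with matrices `tau_eps` (recorded states x genes) and `p`
#'   (recorded states x patterns).
#' @export
geweke_sample <- function(family, N = 20, group_sizes = c(3, 3),
                          n_sweeps = 10000, thin = 10,
                          config = hyperprior_config()) {
  k <- length(group_sizes)
  patterns <- enumerate_partitions(k)
  tabs <- pattern_tables(patterns, k)
  fam_code <- family_code(nid_family(family))
  conc <- rep(config$dirichlet_conc, length(patterns))
  grp <- rep(seq_len(k), group_sizes)
  n <- length(grp)

  params <- prior_param_draw(family, N, k, patterns, config)
  dg <- data_given_params(params, family, N, group_sizes)
  y <- dg$data$values
  st <- list(mu = params$mu, u = dg$u, tau_eps = params$tau_eps,
             nu = params$nu, z = params$z - 1L, p = params$p,
             tau_mu = params$tau_mu)

  n_rec <- n_sweeps %/% thin
  tau_rec <- matrix(NA_real_, n_rec, N)
  p_rec <- matrix(NA_real_, n_rec, length(patterns))
  r <- 0L
  for (s in seq_len(n_sweeps)) {
    st <- .cpp_gibbs_sweep(y, grp - 1L, tabs$block_of, tabs$prec_of,
                           tabs$nblocks, st, fam_code, conc,
                           hyper_vec(config), 1L)
    # exact redraw of the data given (mu, tau_eps, u)
    sd_mat <- 1 / sqrt(st$tau_eps * st$u)
    y <- st$mu[, grp, drop = FALSE] + matrix(rnorm(N * n), N, n) * sd_mat
    if (s %% thin == 0L) {
      r <- r + 1L
      tau_rec[r, ] <- st$tau_eps
      p_rec[r, ] <- st$p
    }
  }
  list(tau_eps = tau_rec, p = p_rec)
}
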
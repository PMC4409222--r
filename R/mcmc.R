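#' MCMC configuration
#'
#' Defaults follow the protocol used for real two-group data: two parallel
#' chains of 20,000 iterations with the first 15,000 discarded as burn-in.
#' Simulation studies typically use shorter single chains (see
#' [simulation_config()]).
#'
#' @param n_iter Total iterations per chain.
#' @param n_burnin Iterations discarded as burn-in (`< n_iter`).
#' @param n_chains Number of parallel chains (>= 1).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; chain `c` uses `seed + c`, so runs are fully
#'   reproducible.
#' @param store_z Keep the full per-iteration trace of per-gene pattern
#'   indicators (needed only for custom trace analysis; posterior
#'   probabilities are accumulated regardless).
#' @param verbose Print progress every 1000 iterations.
#' @param hyper A [hyperprior_config()].
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 20000, n_burnin = 15000, n_chains = 2,
                        thin = 1, seed = 1, store_z = FALSE, verbose = FALSE,
                        hyper = hyperprior_config()) {
  stopifnot(n_burnin < n_iter, n_chains >= 1, thin >= 1)
  structure(list(n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 n_chains = as.integer(n_chains), thin = as.integer(thin),
                 seed = as.integer(seed), store_z = isTRUE(store_z),
                 verbose = isTRUE(verbose), hyper = hyper),
            class = "mcmc_config")
}

# Deterministic chain initialization: group sample means (jittered for
# chains beyond the first), unit latent scales, inverse pooled residual
# variance for the error precisions (floored for degenerate genes), the
# all-equal pattern, uniform mixing probabilities and family-default shapes.
init_state <- function(data, family, patterns, chain = 1L,
                       tau_floor = 1e-8, tau_cap = 1e8) {
  y <- data$values
  N <- nrow(y); k <- n_groups(data); n <- ncol(y)
  grp <- data$groups
  mu <- vapply(seq_len(k),
               function(g) rowMeans(y[, grp == g, drop = FALSE]),
               numeric(N))
  mu <- matrix(mu, N, k)
  if (chain > 1L) mu <- mu + rnorm(N * k, 0, 0.1)
  resid2 <- rowSums((y - mu[, grp, drop = FALSE])^2)
  pooled_var <- resid2 / max(n - k, 1L)
  tau_eps <- pmin(1 / pmax(pooled_var, tau_floor), tau_cap)
  nu <- switch(family,
    normal = matrix(1, N, 2),
    t = matrix(c(5, 1), N, 2, byrow = TRUE),
    slash = matrix(c(2, 1), N, 2, byrow = TRUE),
    cn = matrix(0.5, N, 2),
    laplace = matrix(1, N, 2))
  P <- length(patterns)
  list(mu = mu, u = matrix(1, N, n), tau_eps = tau_eps, nu = nu,
       z = rep(0L, N),  # 0-based pattern index as consumed by the sweep
       p = rep(1 / P, P),
       tau_mu = rep(1 / (mean(mu^2) + 0.01), k + 1L))
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Fits the hierarchical N/I model: per sweep, (i) each gene's equality
#' pattern is drawn from its full conditional with the block means
#' integrated out analytically, then the block means from their conjugate
#' normal full conditionals; (ii) latent scale factors are refreshed from
#' their exact family kernels; (iii) gene error precisions and mean-prior
#' precisions from conjugate gamma updates; (iv) family shapes (conjugate
#' for slash/Laplace, random-walk Metropolis on the log t degrees of
#' freedom, Beta/truncated-gamma for the contaminated normal); (v) pattern
#' mixing probabilities from their Dirichlet full conditional.
#'
#' @param data An [expression_dataset()].
#' @param family An [nid_family()] giving the error family to fit (its
#'   shape values are used only as the chain's initial values; shapes are
#'   sampled per gene).
#' @param config An [mcmc_config()].
#' @return An object of class `nidge_fit` containing accumulated posterior
#'   pattern frequencies, pairwise separation probabilities and mean
#'   differences, monitored scalar traces per chain, and Gelman-Rubin
#'   statistics when more than one chain was run.
#' @export
run_chains <- function(data, family = nid_family("normal"),
                       config = mcmc_config()) {
  if (!inherits(data, "expression_dataset"))
    stop("`data` must be an expression_dataset")
  stopifnot_family(family)
  k <- n_groups(data); N <- n_genes(data)
  patterns <- enumerate_partitions(k)
  tabs <- pattern_tables(patterns, k)
  fam_code <- family_code(family)
  conc <- rep(config$hyper$dirichlet_conc, length(patterns))

  # monitored tau_eps subset: a deterministic random 1% of genes (>= 2)
  set.seed(config$seed)
  n_mon <- max(2L, min(N, ceiling(0.01 * N)))
  tau_idx <- sort(sample.int(N, n_mon))

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch)
    st <- init_state(data, family$family, patterns, chain = ch)
    if (length(family$shape) >= 1L) st$nu[, 1L] <- family$shape[1L]
    if (length(family$shape) >= 2L) st$nu[, 2L] <- family$shape[2L]
    if (config$verbose)
      message("chain ", ch, "/", config$n_chains, " (", family$family, ")")
    chains[[ch]] <- .cpp_run_chain(
      data$values, data$groups - 1L, tabs$block_of, tabs$prec_of,
      tabs$nblocks, st, fam_code, conc, hyper_vec(config$hyper),
      config$n_iter, config$n_burnin, config$thin, tabs$pair_sep, tau_idx,
      config$store_z, config$verbose)
  }

  n_keep <- chains[[1L]]$n_keep
  pattern_counts <- Reduce(`+`, lapply(chains, `[[`, "pattern_counts"))
  pair_prob <- Reduce(`+`, lapply(chains, `[[`, "pair_prob")) /
    config$n_chains
  pair_mean_diff <- Reduce(`+`, lapply(chains, `[[`, "pair_mean_diff")) /
    config$n_chains

  rhat <- NULL
  if (config$n_chains >= 2L) {
    mon <- c(list(p_DE = sapply(chains, function(x) 1 - x$p_trace[, 1L]),
                  deviance = sapply(chains, `[[`, "deviance_trace")),
             setNames(lapply(seq_along(tau_idx), function(j)
               sapply(chains, function(x) x$tau_eps_trace[, j])),
               paste0("tau_eps_", tau_idx)))
    rhat <- vapply(mon, function(tr)
      tryCatch(gelman_rubin(tr), error = function(e) NA_real_),
      numeric(1))
    bad <- rhat[!is.na(rhat) & rhat > 1.1]
    if (length(bad))
      warning("Gelman-Rubin R-hat above 1.1 for: ",
              paste0(names(bad), " (", round(bad, 3), ")", collapse = ", "),
              "; consider longer chains", call. = FALSE)
  }

  structure(list(chains = chains, pattern_counts = pattern_counts,
                 pair_prob = pair_prob, pair_mean_diff = pair_mean_diff,
                 n_keep_total = n_keep * config$n_chains,
                 patterns = patterns, pair_labels = pair_labels(
                   data$group_names), gene_ids = data$gene_ids,
                 group_names = data$group_names, family = family,
                 config = config, rhat = rhat),
            class = "nidge_fit")
}

#' @export
print.nidge_fit <- function(x, ...) {
  cat("<nidge_fit> ", length(x$gene_ids), " genes, ",
      length(x$group_names), " groups, family = ", x$family$family,
      "; ", x$config$n_chains, " chain(s) x ", x$config$n_iter,
      " iterations (", x$n_keep_total, " retained draws)\n", sep = "")
  if (!is.null(x$rhat))
    cat("  max R-hat: ", round(max(x$rhat, na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' \eqn{\hat R = \sqrt{((n-1)/n \cdot W + B/n) / W}} with `W` the mean
#' within-chain variance and `B` = n times the variance of the chain means.
#'
#' @param traces Matrix with one column per chain (iterations in rows), or
#'   a list of equal-length numeric vectors.
#' @return The scalar \eqn{\hat R}.
#' @export
gelman_rubin <- function(traces) {
  if (is.list(traces)) traces <- do.call(cbind, traces)
  traces <- as.matrix(traces)
  if (ncol(traces) < 2L) stop("at least two chains are required")
  if (nrow(traces) < 2L) stop("chains must have length >= 2")
  n <- nrow(traces)
  W <- mean(apply(traces, 2L, var))
  if (!is.finite(W) || W <= 0)
    stop("within-chain variance is zero; R-hat is undefined")
  B <- n * var(colMeans(traces))
  sqrt(((n - 1) / n * W + B / n) / W)
}
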
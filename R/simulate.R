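#' Simulation-study configuration
#'
#' Describes one synthetic two-group power study.  Defaults reproduce the
#' contaminated-normal study design: N = 1000 genes over M = 100
#' replications, group sizes 27 and 11, common baseline location 14 on the
#' log-intensity scale, unit error variance, contaminated-normal errors
#' with contamination weight 0.1, and 5\% of genes shifted upwards by
#' `delta` in group 1 only.
#'
#' @param N Genes per replication.
#' @param M Replications.
#' @param group_sizes Two replicate counts `(n1, n2)`.
#' @param base_mu Common baseline location (log-intensity units).
#' @param sigma Error variance at latent scale u = 1.
#' @param error_family [nid_family()] generating the errors.
#' @param delta Location shift added to group 1 for truly DE genes.
#' @param de_fraction Fraction of DE genes; exactly `round(N *
#'   de_fraction)` genes are shifted per replication so the TPR/FPR
#'   denominators `N p` and `N (1 - p)` are exact.
#' @param fit_families List of [nid_family()] objects (or family name
#'   strings) to fit to each replication.
#' @param mcmc An [mcmc_config()]; simulation studies default to a single
#'   chain of 15,000 iterations with 10,000 burn-in.
#' @param seed Master seed; every replication derives its own generation
#'   and fitting streams from it.
#' @param redraw_de Redraw the DE gene set each replication (default);
#'   `FALSE` fixes one set drawn from `seed` for all replications.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(N = 1000, M = 100, group_sizes = c(27, 11),
                              base_mu = 14, sigma = 1,
                              error_family = nid_family("cn", c(0.1, 0.10)),
                              delta = 3, de_fraction = 0.05,
                              fit_families = list("normal", "t", "slash",
                                                  "cn", "laplace"),
                              mcmc = mcmc_config(n_iter = 15000,
                                                 n_burnin = 10000,
                                                 n_chains = 1),
                              seed = 1, redraw_de = TRUE) {
  stopifnot(de_fraction > 0, de_fraction < 1, round(N * de_fraction) >= 1,
            length(group_sizes) == 2, all(group_sizes >= 2),
            is.finite(delta), sigma > 0)
  stopifnot_family(error_family)
  fit_families <- lapply(fit_families, function(f)
    if (is.character(f)) nid_family(f) else stopifnot_family(f))
  structure(list(N = as.integer(N), M = as.integer(M),
                 group_sizes = as.integer(group_sizes), base_mu = base_mu,
                 sigma = sigma, error_family = error_family, delta = delta,
                 de_fraction = de_fraction, fit_families = fit_families,
                 mcmc = mcmc, seed = as.integer(seed),
                 redraw_de = isTRUE(redraw_de)),
            class = "simulation_config")
}

#' Generate one simulated replication
#'
#' Draws `Y_isr = mu_is + e_isr` with errors from the configured N/I
#' family; exactly `round(N * de_fraction)` randomly chosen genes have
#' their group-1 location shifted to `base_mu + delta`, group 2 stays at
#' `base_mu`.  The random stream is derived from `(seed,
#' replication_index)` so replications are independent and reproducible in
#' isolation.
#'
#' @param config A [simulation_config()].
#' @param replication_index Which replication (1..M).
#' @return `list(data, truth)` with `truth` the 0/1 DE indicator per gene.
#' @export
generate_dataset <- function(config, replication_index = 1L) {
  stopifnot(inherits(config, "simulation_config"),
            replication_index >= 1L, replication_index <= config$M)
  N <- config$N
  n_de <- round(N * config$de_fraction)
  if (!config$redraw_de) {
    set.seed(config$seed)
    de_genes <- sample.int(N, n_de)
  }
  set.seed(config$seed + 7919L * as.integer(replication_index))
  if (config$redraw_de) de_genes <- sample.int(N, n_de)
  truth <- integer(N)
  truth[de_genes] <- 1L
  n <- sum(config$group_sizes)
  grp <- rep(1:2, config$group_sizes)
  mu <- matrix(config$base_mu, N, 2)
  mu[de_genes, 1L] <- config$base_mu + config$delta
  eps <- matrix(rnid(N * n, 0, config$sigma, config$error_family), N, n)
  y <- mu[, grp] + eps
  list(data = expression_dataset(y, grp), truth = truth)
}

#' Per-replication detection metrics
#'
#' Exact confusion-matrix rates against the known truth:
#' \eqn{TPR_k = \sum_i I^{Real}_{ik} I^{Method}_{ik} / (N p)},
#' \eqn{FPR_k = \sum_i (1 - I^{Real}_{ik}) I^{Method}_{ik} / (N(1-p))},
#' \eqn{TDR_k = \sum_i I^{Real}_{ik} I^{Method}_{ik} / \sum_i
#' I^{Method}_{ik}}, plus the truth-based ROC area of the posterior
#' probabilities.  With no calls, TDR is undefined and returned as `NA`.
#'
#' @param truth 0/1 truth labels.
#' @param calls 0/1 method calls (posterior probability above threshold).
#' @param pi Posterior DE probabilities (for the AUC).
#' @param config The [simulation_config()] (supplies `de_fraction`).
#' @return `c(TPR, FPR, TDR, AUC)`; `TDR` may be `NA`.
#' @export
replication_metrics <- function(truth, calls, pi, config) {
  stopifnot(length(truth) == length(calls), length(pi) == length(truth))
  truth <- as.integer(truth); calls <- as.integer(calls)
  N <- length(truth); p <- config$de_fraction
  tp <- sum(truth * calls)
  fp <- sum((1L - truth) * calls)
  c(TPR = tp / (N * p), FPR = fp / (N * (1 - p)),
    TDR = if (sum(calls) > 0L) tp / sum(calls) else NA_real_,
    AUC = truth_roc_auc(pi, truth))
}

#' Run a full simulation study
#'
#' For each replication: generate a dataset, fit each requested error
#' family by MCMC, convert retained draws to posterior DE probabilities,
#' call genes at `kappa` and score against the truth.  Results are averaged
#' over replications with Monte-Carlo standard errors.
#'
#' @param config A [simulation_config()].
#' @param kappa Posterior call threshold (default 0.5).
#' @param checkpoint_dir Optional directory; per-replication results are
#'   saved there and reloaded on a re-run so interrupted studies resume.
#' @param verbose Print per-replication progress.
#' @return A list of class `simulation_result`: `per_replication` (data
#'   frame of TPR/FPR/TDR/AUC per replication and family), `summary` (per
#'   family: means and MC standard errors, plus the count of replications
#'   where TDR was undefined), and the `config`.
#' @export
run_study <- function(config, kappa = 0.5, checkpoint_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  fams <- vapply(config$fit_families, `[[`, "", "family")
  rows <- list()
  for (k in seq_len(config$M)) {
    ck_file <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, sprintf("rep_%03d.rds", k)) else NULL
    if (!is.null(ck_file) && file.exists(ck_file)) {
      rows[[k]] <- readRDS(ck_file)
      next
    }
    gen <- generate_dataset(config, k)
    rep_rows <- vector("list", length(fams))
    for (fi in seq_along(fams)) {
      mc <- config$mcmc
      mc$seed <- config$seed + 104729L + 100L * k + fi
      fit <- tryCatch(
        run_chains(gen$data, config$fit_families[[fi]], mc),
        error = function(e) e)
      if (inherits(fit, "error")) {
        warning("replication ", k, ", family ", fams[fi], " failed: ",
                conditionMessage(fit), "; replication excluded",
                call. = FALSE)
        rep_rows[[fi]] <- data.frame(replication = k, family = fams[fi],
                                     TPR = NA, FPR = NA, TDR = NA,
                                     AUC = NA, failed = TRUE)
        next
      }
      post <- de_probability(fit)
      m <- replication_metrics(gen$truth, post$pi > kappa, post$pi, config)
      rep_rows[[fi]] <- data.frame(replication = k, family = fams[fi],
                                   TPR = m[["TPR"]], FPR = m[["FPR"]],
                                   TDR = m[["TDR"]], AUC = m[["AUC"]],
                                   failed = FALSE)
    }
    rows[[k]] <- do.call(rbind, rep_rows)
    if (!is.null(ck_file)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(rows[[k]], ck_file)
    }
    if (verbose)
      message("replication ", k, "/", config$M, " done")
  }
  per_rep <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(unique(per_rep$family), function(f) {
    d <- per_rep[per_rep$family == f & !d_failed(per_rep, f), ]
    mse <- function(x) {
      x <- x[!is.na(x)]
      c(mean(x), if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_)
    }
    tpr <- mse(d$TPR); fpr <- mse(d$FPR); tdr <- mse(d$TDR); auc <- mse(d$AUC)
    data.frame(family = f, TPR = tpr[1], FPR = fpr[1], TDR = tdr[1],
               AUC = auc[1], TPR_se = tpr[2], FPR_se = fpr[2],
               TDR_se = tdr[2], AUC_se = auc[2],
               n_used = nrow(d), n_tdr_undefined = sum(is.na(d$TDR)),
               n_failed = sum(d_failed(per_rep, f)))
  }))
  rownames(summ) <- NULL
  structure(list(per_replication = per_rep, summary = summ,
                 kappa = kappa, config = config),
            class = "simulation_result")
}

d_failed <- function(per_rep, f) per_rep$family == f & per_rep$failed

#' @export
print.simulation_result <- function(x, ...) {
  cfg <- x$config
  cat("<simulation_result> N=", cfg$N, ", M=", cfg$M, ", delta=",
      cfg$delta, ", errors=", cfg$error_family$family, "(",
      paste(signif(cfg$error_family$shape, 3), collapse = ","),
      "), kappa=", x$kappa, "\n", sep = "")
  print(x$summary[, c("family", "TPR", "FPR", "TDR", "AUC")], digits = 4)
  invisible(x)
}
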
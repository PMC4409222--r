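#' Posterior differential-expression probabilities
#'
#' Per-gene posterior probability of differential expression,
#' \eqn{\pi_i = P(\text{not all group means equal} \mid \text{data})},
#' computed as the fraction of retained draws (pooled over chains) in which
#' gene i's equality pattern is not the all-equal one.  For more than two
#' groups the union-intersection decomposition is also reported: one
#' posterior probability per group pair, the fraction of draws whose
#' pattern puts that pair in different blocks.
#'
#' @param fit A [run_chains()] result.
#' @return An object of class `posterior_summary`: `gene_ids`, `pi`,
#'   `pairwise` (N x pairs matrix), `mean_diff` (posterior mean of
#'   \eqn{\mu_{is} - \mu_{is'}} per pair), `pattern_prob` (N x patterns),
#'   `rhat`.
#' @export
de_probability <- function(fit) {
  if (!inherits(fit, "nidge_fit")) stop("`fit` must be a nidge_fit")
  if (fit$n_keep_total < 1L) stop("no retained draws")
  pattern_prob <- fit$pattern_counts / fit$n_keep_total
  pi <- 1 - pattern_prob[, 1L]
  pairwise <- fit$pair_prob
  colnames(pairwise) <- fit$pair_labels
  mean_diff <- fit$pair_mean_diff
  colnames(mean_diff) <- fit$pair_labels
  structure(list(gene_ids = fit$gene_ids, pi = pi, pairwise = pairwise,
                 mean_diff = mean_diff, pattern_prob = pattern_prob,
                 pattern_mix = colMeans(do.call(rbind, lapply(
                   fit$chains, `[[`, "p_trace"))),
                 rhat = fit$rhat, family = fit$family$family),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary> ", length(x$pi), " genes (family = ", x$family,
      ")\n  P(DE) quartiles: ",
      paste(signif(quantile(x$pi, c(0.25, 0.5, 0.75)), 3), collapse = " / "),
      "\n", sep = "")
  invisible(x)
}

#' Bayesian decision rates at a posterior threshold
#'
#' With calls \eqn{r_i = I(\pi_i > \kappa)}, the Bayesian rates weight each
#' gene by its posterior class probabilities:
#' \deqn{bFPR = \frac{\sum_i (1-\pi_i) r_i}{\sum_i (1-\pi_i)}, \quad
#'       bTPR = \frac{\sum_i \pi_i r_i}{\sum_i \pi_i}, \quad
#'       bFDR = \frac{\sum_i (1-\pi_i) r_i}{\sum_i r_i},}
#' with \eqn{bTNR = 1 - bFPR} and \eqn{bFNR = 1 - bTPR}.  When no gene is
#' called, bFDR is reported as 0 with `no_calls = TRUE`.
#'
#' @param pi Per-gene posterior DE probabilities, or a `posterior_summary`
#'   (its global probabilities are used).
#' @param kappa Posterior threshold in \[0, 1\]; calls use the strict
#'   inequality \eqn{\pi_i > \kappa}.
#' @return A list of class `decision_report`: `kappa`, `calls`, `n_called`,
#'   `bFDR`, `bFPR`, `bTPR`, `bTNR`, `bFNR`, `no_calls`.
#' @examples
#' bayes_rates(c(0.9, 0.8, 0.3, 0.1), 0.5)  # bFDR 0.15
#' @export
bayes_rates <- function(pi, kappa) {
  if (inherits(pi, "posterior_summary")) pi <- pi$pi
  stopifnot(kappa >= 0, kappa <= 1, all(pi >= 0 & pi <= 1))
  r <- pi > kappa
  no_calls <- !any(r)
  bFPR <- if (sum(1 - pi) > 0) sum((1 - pi)[r]) / sum(1 - pi) else 0
  bTPR <- if (sum(pi) > 0) sum(pi[r]) / sum(pi) else 0
  bFDR <- if (no_calls) 0 else sum((1 - pi)[r]) / sum(r)
  structure(list(kappa = kappa, calls = r, n_called = sum(r), bFDR = bFDR,
                 bFPR = bFPR, bTPR = bTPR, bTNR = 1 - bFPR, bFNR = 1 - bTPR,
                 no_calls = no_calls),
            class = "decision_report")
}

#' @export
print.decision_report <- function(x, ...) {
  cat(sprintf(
    "<decision_report> kappa=%.3g: %d called; bFDR=%.4f bFPR=%.4f bTPR=%.4f bTNR=%.4f bFNR=%.4f%s\n",
    x$kappa, x$n_called, x$bFDR, x$bFPR, x$bTPR, x$bTNR, x$bFNR,
    if (x$no_calls) " [no calls]" else ""))
  invisible(x)
}

#' Posterior-weighted ROC curve and AUC
#'
#' Evaluates (bFPR(kappa), bTPR(kappa)) over the threshold grid {0, each
#' distinct probability, 1}, orients the curve from (0,0) to (1,1), and
#' integrates by the trapezoid rule.  When all probabilities coincide the
#' curve is degenerate (two points), the AUC is 0.5 and the result is
#' flagged.
#'
#' @inheritParams bayes_rates
#' @return A list of class `roc_curve`: `points` (data frame with `kappa`,
#'   `bFPR`, `bTPR`), `auc`, `degenerate`.
#' @export
roc_auc <- function(pi) {
  if (inherits(pi, "posterior_summary")) pi <- pi$pi
  if (length(pi) < 2L) stop("at least 2 genes are required")
  grid <- sort(unique(c(0, pi, 1)))
  pts <- t(vapply(grid, function(k) {
    b <- bayes_rates(pi, k)
    c(kappa = k, bFPR = b$bFPR, bTPR = b$bTPR)
  }, numeric(3)))
  pts <- as.data.frame(pts)
  # kappa descending runs the curve from (0,0) (kappa=1) towards (1,1);
  # both endpoints are appended (calls are strict, so kappa = 0 leaves any
  # pi = 0 gene uncalled and the curve needs its (1,1) anchor)
  pts <- rbind(data.frame(kappa = NA_real_, bFPR = 0, bTPR = 0),
               pts[order(-pts$kappa), ],
               data.frame(kappa = NA_real_, bFPR = 1, bTPR = 1))
  rownames(pts) <- NULL
  degenerate <- length(unique(pi)) == 1L
  auc <- if (degenerate) 0.5 else {
    x <- pts$bFPR; y <- pts$bTPR
    sum((x[-1] - x[-length(x)]) * (y[-1] + y[-length(y)]) / 2)
  }
  structure(list(points = pts, auc = auc, degenerate = degenerate),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", nrow(x$points), " points, AUC = ",
      signif(x$auc, 4), if (x$degenerate) " [degenerate]" else "", "\n",
      sep = "")
  invisible(x)
}

#' Truth-based ROC area
#'
#' Frequentist AUC of the probabilities against known 0/1 labels (used in
#' simulation studies where the truth is known): the Mann-Whitney rank
#' statistic with half credit for ties.
#'
#' @param pi Per-gene scores (posterior DE probabilities).
#' @param truth 0/1 vector of true DE status; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' truth_roc_auc(c(0.9, 0.3, 0.8, 0.1), c(1, 1, 0, 0))  # 0.75
#' @export
truth_roc_auc <- function(pi, truth) {
  truth <- as.integer(truth)
  if (length(pi) != length(truth)) stop("lengths differ")
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present in `truth`")
  r <- rank(pi, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
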
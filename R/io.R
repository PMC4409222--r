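#' Read an expression matrix and group assignment from disk
#'
#' The matrix file is tab-delimited (comma autodetected from the header
#' line and logged), genes in rows, first column gene ids, remaining
#' columns samples, with a header row of sample names.  The groups file has
#' two columns, sample name and group label, header optional.  Values are
#' expected to be already log-transformed.
#'
#' @param matrix_path Path to the expression matrix.
#' @param groups_path Path to the sample-to-group table.
#' @return An [expression_dataset()]; groups ordered by first appearance
#'   among the matrix columns.
#' @export
read_dataset <- function(matrix_path, groups_path) {
  for (p in c(matrix_path, groups_path))
    if (!file.exists(p)) stop("file not found: ", p)
  sep <- detect_sep(matrix_path)
  tab <- read.delim(matrix_path, sep = sep, header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("matrix must have a gene-id column and >= 2 samples")
  gene_ids <- as.character(tab[[1L]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  body <- tab[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("non-numeric cell at row ", bad[1L], ", sample '",
             colnames(body)[j], "'")
      body[[j]] <- vn
    }
    if (anyNA(body[[j]]))
      stop("missing value at row ", which(is.na(body[[j]]))[1L],
           ", sample '", colnames(body)[j], "'")
  }
  y <- as.matrix(body)

  gsep <- detect_sep(groups_path)
  gtab <- read.delim(groups_path, sep = gsep, header = FALSE,
                     stringsAsFactors = FALSE)
  if (tolower(gtab[1, 1]) %in% c("sample", "sample_name", "name"))
    gtab <- gtab[-1L, , drop = FALSE]
  if (ncol(gtab) < 2L) stop("groups file needs two columns: sample, group")
  idx <- match(colnames(y), gtab[[1L]])
  if (anyNA(idx))
    stop("sample(s) missing from the groups file: ",
         paste(colnames(y)[is.na(idx)], collapse = ", "))
  expression_dataset(y, gtab[[2L]][idx], gene_ids = gene_ids)
}

#' Write retained MCMC draws to a compressed columnar table
#'
#' One row per retained iteration per chain: chain and iteration indices,
#' mixing probabilities per pattern, mean-prior precisions, the monitored
#' subset of gene error precisions, the conditional deviance, and (when
#' the fit was run with `store_z = TRUE`) the per-gene pattern indicators.
#'
#' @param fit A [run_chains()] result.
#' @param path Output path; written gzip-compressed (a `.gz` suffix is
#'   conventional).
#' @return Invisibly, `path`.
#' @export
write_draws <- function(fit, path) {
  if (!inherits(fit, "nidge_fit")) stop("`fit` must be a nidge_fit")
  tabs <- lapply(seq_along(fit$chains), function(ci) {
    ch <- fit$chains[[ci]]
    d <- data.frame(chain = ci, iteration = seq_len(ch$n_keep))
    p <- as.data.frame(ch$p_trace)
    names(p) <- paste0("p_pattern", seq_len(ncol(p)))
    tm <- as.data.frame(ch$tau_mu_trace)
    names(tm) <- c("tau_mu_shared",
                   paste0("tau_mu_group", seq_len(ncol(tm) - 1L)))
    d <- cbind(d, p, tm, deviance = ch$deviance_trace)
    if (ncol(ch$tau_eps_trace)) {
      te <- as.data.frame(ch$tau_eps_trace)
      names(te) <- paste0("tau_eps_mon", seq_len(ncol(te)))
      d <- cbind(d, te)
    }
    if (nrow(ch$z_trace)) {
      z <- as.data.frame(ch$z_trace)
      names(z) <- paste0("z_", fit$gene_ids)
      d <- cbind(d, z)
    }
    d
  })
  con <- gzfile(path, "w")
  on.exit(close(con))
  write.table(do.call(rbind, tabs), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("\t", header) && grepl(",", header)) {
    message("comma-separated input detected: ", path)
    ","
  } else "\t"
}

#' Write fit results to a directory
#'
#' Emits `results.tsv` (per gene: posterior DE probability, pairwise
#' probabilities and mean differences for k > 2, and the call at each
#' threshold), `decisions.tsv` (one row per threshold with the call count
#' and Bayesian rates, the layout of a decision-rate table),
#' `roc.tsv` (the posterior-weighted ROC points) and `manifest.json`
#' (family, thresholds, convergence summary).
#'
#' @param summary A [de_probability()] result.
#' @param out_dir Output directory; refuses to overwrite an existing one
#'   unless `force = TRUE`.
#' @param kappa Thresholds for the decision table.
#' @param force Overwrite an existing directory.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(summary, out_dir,
                          kappa = c(0.5, 0.7, 0.9, 0.95), force = FALSE) {
  if (!inherits(summary, "posterior_summary"))
    stop("`summary` must be a posterior_summary")
  if (length(summary$pi) == 0L) stop("empty gene set; nothing to write")
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory exists and is not empty; use force = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  res <- data.frame(gene_id = summary$gene_ids, pi = summary$pi,
                    check.names = FALSE)
  if (ncol(summary$pairwise) > 1L) {
    pw <- as.data.frame(summary$pairwise)
    names(pw) <- paste0("pi_", colnames(summary$pairwise))
    res <- cbind(res, pw)
  }
  md <- as.data.frame(summary$mean_diff)
  names(md) <- paste0("mean_diff_", colnames(summary$mean_diff))
  res <- cbind(res, md)
  for (k in kappa)
    res[[sprintf("call_%g", k)]] <- as.integer(summary$pi > k)
  f_res <- file.path(out_dir, "results.tsv")
  write.table(res, f_res, sep = "\t", quote = FALSE, row.names = FALSE)

  dec <- do.call(rbind, lapply(kappa, function(k) {
    b <- bayes_rates(summary$pi, k)
    data.frame(kappa = k, n_called = b$n_called, bFDR = b$bFDR,
               bTNR = b$bTNR, bFNR = b$bFNR, bFPR = b$bFPR, bTPR = b$bTPR,
               no_calls = b$no_calls)
  }))
  f_dec <- file.path(out_dir, "decisions.tsv")
  write.table(dec, f_dec, sep = "\t", quote = FALSE, row.names = FALSE)

  roc <- roc_auc(summary$pi)
  f_roc <- file.path(out_dir, "roc.tsv")
  write.table(roc$points, f_roc, sep = "\t", quote = FALSE,
              row.names = FALSE)

  f_man <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(family = summary$family, n_genes = length(summary$pi),
         kappa = kappa, auc_posterior_weighted = roc$auc,
         rhat = if (is.null(summary$rhat)) NULL else
           list(max = max(summary$rhat, na.rm = TRUE),
                values = as.list(summary$rhat)),
         pattern_mixing_probabilities = summary$pattern_mix),
    f_man, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(c(f_res, f_dec, f_roc, f_man))
}
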
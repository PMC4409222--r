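#' Expression dataset container
#'
#' Bundles a gene-by-sample matrix of log-transformed intensities (or log
#' ratios) with the group assignment of each sample column.  Groups are
#' ordered by first appearance; every group must have at least two
#' replicates and no missing values are allowed.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param groups Vector (character/factor/integer) of length `ncol(values)`
#'   assigning each sample to a group.
#' @param gene_ids Optional gene identifiers; defaults to rownames or
#'   `gene_1 ... gene_N`.
#' @return An object of class `expression_dataset` with elements `values`,
#'   `groups` (integer codes 1..k), `group_names`, `group_sizes`, `gene_ids`.
#' @examples
#' y <- matrix(rnorm(12), nrow = 3)
#' expression_dataset(y, c("A", "A", "B", "B"))
#' @export
expression_dataset <- function(values, groups, gene_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite; missing entries are not allowed")
  if (length(groups) != ncol(values))
    stop("`groups` must assign every sample column exactly once")
  group_names <- unique(as.character(groups))
  g <- match(as.character(groups), group_names)
  sizes <- tabulate(g, nbins = length(group_names))
  if (length(group_names) < 2L)
    stop("at least two groups are required")
  if (any(sizes < 2L))
    stop("every group needs at least 2 replicates; offending group(s): ",
         paste(group_names[sizes < 2L], collapse = ", "))
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  }
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  structure(list(values = unname(values), groups = g,
                 group_names = group_names, group_sizes = sizes,
                 gene_ids = as.character(gene_ids)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", nrow(x$values), " genes x ",
      ncol(x$values), " samples; groups: ",
      paste0(x$group_names, " (n=", x$group_sizes, ")", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

n_genes <- function(data) nrow(data$values)
n_groups <- function(data) length(data$group_sizes)
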
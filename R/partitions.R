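#' Enumerate group-mean equality patterns
#'
#' All set partitions of the groups `1..k`, each one an assignment of groups
#' to blocks of equal means.  The hypothesis that a gene is not
#' differentially expressed is the all-equal partition; a gene is
#' differentially expressed when at least one pair of groups falls in
#' different blocks (the union-intersection view of the k-group test).
#' Patterns are returned in the lexicographic order of their restricted
#' growth strings, which puts the all-equal pattern first; for `k = 3` this
#' gives the conventional five patterns
#' \eqn{\mu_1=\mu_2=\mu_3}, \eqn{\mu_1=\mu_2\ne\mu_3},
#' \eqn{\mu_2\ne\mu_1=\mu_3}, \eqn{\mu_1\ne\mu_2=\mu_3},
#' \eqn{\mu_1\ne\mu_2\ne\mu_3}.
#'
#' @param k Number of groups, between 2 and 5 (Bell-number growth makes
#'   larger `k` impractical for the mixture prior).
#' @return A list of patterns; each has `assignment` (block index per
#'   group), `blocks` (list of group-index vectors) and `is_null`.
#' @examples
#' length(enumerate_partitions(3))  # 5
#' @export
enumerate_partitions <- function(k) {
  if (!is.numeric(k) || k < 2 || k > 5)
    stop("supported group counts are 2 <= k <= 5")
  k <- as.integer(k)
  # restricted growth strings, generated in lexicographic order
  out <- list()
  rec <- function(a, maxb) {
    if (length(a) == k) {
      blocks <- split(seq_len(k), a)
      names(blocks) <- NULL
      out[[length(out) + 1L]] <<- structure(
        list(assignment = a, blocks = blocks, is_null = maxb == 1L),
        class = "nid_pattern")
      return(invisible(NULL))
    }
    for (b in seq_len(maxb + 1L)) rec(c(a, b), max(maxb, b))
  }
  rec(1L, 1L)
  out
}

#' Pairwise separation map of a pattern
#'
#' Which group pairs a pattern declares different: entry `(s, s')` is `TRUE`
#' iff groups `s` and `s'` lie in different blocks.  The all-equal pattern
#' maps to the all-`FALSE` matrix.
#'
#' @param pattern A pattern from [enumerate_partitions()].
#' @return A `k x k` logical matrix with `FALSE` diagonal.
#' @export
pattern_pairwise_map <- function(pattern) {
  a <- pattern$assignment
  outer(a, a, `!=`)
}

#' @export
print.nid_pattern <- function(x, ...) {
  cat("<pattern> ",
      paste(vapply(x$blocks, paste, "", collapse = "="), collapse = " | "),
      if (x$is_null) "  (null)" else "", "\n", sep = "")
  invisible(x)
}

# Encodings consumed by the C++ sweep: block index per group (0-based),
# precision index per block slot (0 = shared multi-group precision,
# s = per-group precision for the singleton {s}), and block counts.
pattern_tables <- function(patterns, k) {
  P <- length(patterns)
  block_of <- matrix(0L, P, k)
  prec_of <- matrix(-1L, P, k)
  nblocks <- integer(P)
  for (j in seq_len(P)) {
    a <- patterns[[j]]$assignment
    block_of[j, ] <- a - 1L
    nblocks[j] <- max(a)
    for (b in seq_len(max(a))) {
      members <- which(a == b)
      prec_of[j, b] <- if (length(members) == 1L) members else 0L
    }
  }
  # pairwise separation indicator per pattern, pairs in (s < s') order
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  pair_sep <- matrix(0L, P, nrow(pairs))
  for (j in seq_len(P)) {
    a <- patterns[[j]]$assignment
    pair_sep[j, ] <- as.integer(a[pairs[, 1L]] != a[pairs[, 2L]])
  }
  list(block_of = block_of, prec_of = prec_of, nblocks = nblocks,
       pair_sep = pair_sep, pairs = pairs)
}

pair_labels <- function(group_names) {
  k <- length(group_names)
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  paste0(group_names[pairs[, 1L]], "_vs_", group_names[pairs[, 2L]])
}
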
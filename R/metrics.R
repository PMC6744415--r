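#' Coverage of a partition
#'
#' Fraction of edge instances with both endpoints in the same block,
#' \eqn{\sum_r m_{rr} / 2m}. Multi-edges count with multiplicity and each
#' self-loop counts once, as a within-block edge. An ideal assortative
#' partition in which no edge crosses a block boundary has coverage 1; a
#' perfect bipartition of a bipartite graph has coverage 0.
#'
#' @param G a [multigraph()].
#' @param g a partition of the nodes of `G`.
#' @return A number in `[0, 1]`.
#' @export
coverage <- function(G, g) {
  stopifnot(inherits(G, "multigraph"))
  if (G$m == 0) stop("coverage undefined on an empty graph")
  bs <- block_summary(G, g)
  sum(diag(bs$m)) / (2 * G$m)
}

#' Newman modularity of a partition
#'
#' The multigraph- and self-loop-aware form
#' \deqn{Q = \sum_r \left[\frac{m_{rr}}{2m} -
#'   \left(\frac{\kappa_r}{2m}\right)^2\right],}
#' comparing the within-block edge fraction to its expectation under a
#' degree-preserving random multigraph.
#'
#' @inheritParams coverage
#' @return A number in `[-1, 1]`; 0 for the single-block partition.
#' @export
modularity_score <- function(G, g) {
  stopifnot(inherits(G, "multigraph"))
  if (G$m < 1) stop("modularity undefined without edges")
  bs <- block_summary(G, g)
  m2 <- 2 * G$m
  sum(diag(bs$m) / m2 - (bs$kappa / m2)^2)
}

# canonical relabelling by order of first appearance; two partitions are
# equal up to label permutation iff their canonical forms are identical
canonical_labels <- function(gv) match(gv, unique(gv))

#' Compare a partition against a reference
#'
#' Node agreement maximized over block-label permutations (exhaustive over
#' the `B!` permutations; supported for `B <= 8`), plus an exact match flag.
#'
#' @param g,ref partitions over the same node set with the same number of
#'   blocks.
#' @return A list with `matches_reference` (logical) and `node_agreement`
#'   (fraction of nodes correctly labelled under the best permutation).
#' @export
match_partitions <- function(g, ref) {
  if (!setequal(names(g), names(ref))) stop("partitions cover different node sets")
  B <- max(n_blocks(g), n_blocks(ref))
  if (B > 8L) stop("exhaustive label matching supported for B <= 8")
  gv <- as.integer(unclass(g))
  rv <- as.integer(unclass(ref)[names(g)])
  matches <- identical(canonical_labels(gv), canonical_labels(rv))
  best <- 0
  for (p in seq_len(nrow(pm <- permutations(B)))) {
    best <- max(best, mean(pm[p, gv] == rv))
  }
  list(matches_reference = matches, node_agreement = best)
}

# all permutations of 1..B as rows
permutations <- function(B) {
  if (B == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(B - 1L)
  out <- matrix(0L, nrow(sub) * B, B)
  row <- 0L
  for (k in seq_len(B)) {
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      rest <- sub[r, ] + (sub[r, ] >= k)
      out[row, ] <- c(k, rest)
    }
  }
  out
}

#' Score a partition against a graph and optional ground truth
#'
#' Convenience bundle of [coverage()], [modularity_score()] and
#' [match_partitions()].
#'
#' @inheritParams coverage
#' @param reference optional ground-truth partition.
#' @return A list of class `"partition_score"` with `coverage`,
#'   `modularity`, and (if a reference is given) `matches_reference` and
#'   `node_agreement`.
#' @export
score_partition <- function(G, g, reference = NULL) {
  out <- list(coverage = coverage(G, g), modularity = modularity_score(G, g))
  if (!is.null(reference)) {
    out <- c(out, match_partitions(g, reference))
  }
  structure(out, class = "partition_score")
}

#' @export
print.partition_score <- function(x, ...) {
  cat(sprintf("coverage = %.4f, modularity = %.4f\n", x$coverage, x$modularity))
  if (!is.null(x$matches_reference)) {
    cat(sprintf("reference: %s (agreement %.4f)\n",
                if (x$matches_reference) "matched" else "not matched",
                x$node_agreement))
  }
  invisible(x)
}
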
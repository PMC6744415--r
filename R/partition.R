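#' Block partitions
#'
#' A partition assigns every node to exactly one of `B` blocks. Internally a
#' partition is a named integer vector with values in `1..B` and an
#' attribute `B`; block labels are arbitrary and only defined up to
#' permutation.
#'
#' @param x a named vector of block labels (integer, character or factor),
#'   one entry per node.
#' @param B number of blocks; defaults to the number of distinct labels.
#' @return A named integer vector of class `"block_partition"` with
#'   attribute `B`.
#' @export
as_partition <- function(x, B = NULL) {
  if (is.null(names(x))) stop("partition must be named by node identifiers")
  if (anyDuplicated(names(x))) stop("duplicate node in partition")
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    suppressWarnings(xi <- as.integer(x))
    g <- if (anyNA(xi)) match(x, sort(unique(x))) else xi
  } else {
    g <- as.integer(x)
  }
  lev <- sort(unique(g))
  g <- match(g, lev)  # compress to 1..#levels
  if (is.null(B)) B <- length(lev)
  if (B < length(lev)) stop("more distinct labels than blocks B")
  structure(stats::setNames(g, names(x)), B = as.integer(B),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  B <- n_blocks(x)
  cat(sprintf("Partition of %d nodes into %d blocks (sizes: %s)\n",
              length(x), B,
              paste(tabulate(unclass(x), B), collapse = ", ")))
  invisible(x)
}

#' Number of blocks of a partition
#' @param g a partition.
#' @return Integer block count.
#' @export
n_blocks <- function(g) {
  B <- attr(g, "B")
  if (is.null(B)) B <- max(as.integer(g)) else as.integer(B)
  B
}

# internal: partition aligned to a graph's node order, validated
align_partition <- function(g, G) {
  gv <- unclass(g)[G$nodes]
  if (anyNA(gv)) {
    miss <- G$nodes[is.na(gv)]
    stop("nodes missing from partition: ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  as.integer(gv)
}

#' Draw a uniform random partition
#'
#' Uniform over all assignments of `nodes` to `B` labelled blocks; when
#' `nonempty = TRUE`, uniform over assignments with no empty block
#' (rejection sampling).
#'
#' @param nodes character vector of node identifiers.
#' @param B number of blocks.
#' @param nonempty require every block non-empty (default `TRUE`).
#' @return A [as_partition()] object.
#' @export
random_partition <- function(nodes, B, nonempty = TRUE) {
  n <- length(nodes)
  if (nonempty && n < B) stop("cannot fill ", B, " blocks with ", n, " nodes")
  repeat {
    g <- sample.int(B, n, replace = TRUE)
    if (!nonempty || length(unique(g)) == B) break
  }
  as_partition(stats::setNames(g, nodes), B = B)
}

#' Read / write partition files
#'
#' Two-column whitespace-separated text, `node_id block_label`, one node per
#' line; `#` starts a comment. Round-trips losslessly for integer labels.
#'
#' @param path file path.
#' @param graph optional [multigraph()]; if given, the partition must cover
#'   exactly its nodes.
#' @param B optional block count (defaults to the number of distinct labels).
#' @return `read_partition` returns a [as_partition()] object.
#' @export
read_partition <- function(path, graph = NULL, B = NULL) {
  lines <- readLines(path, warn = FALSE)
  body <- trimws(sub("#.*$", "", lines))
  idx <- which(nzchar(body))
  if (length(idx) == 0L) stop("empty partition file '", path, "'")
  toks <- strsplit(body[idx], "[ \t]+")
  if (any(lengths(toks) < 2L)) {
    bad <- idx[which(lengths(toks) < 2L)[1L]]
    stop(sprintf("malformed partition line %d in '%s'", bad, path))
  }
  node <- vapply(toks, `[[`, "", 1L)
  lab <- vapply(toks, `[[`, "", 2L)
  if (anyDuplicated(node)) {
    stop("duplicate node '", node[duplicated(node)][1L], "' in '", path, "'")
  }
  g <- as_partition(stats::setNames(lab, node), B = B)
  if (!is.null(graph)) {
    unknown <- setdiff(node, graph$nodes)
    if (length(unknown)) {
      stop("partition names unknown nodes: ", paste(utils::head(unknown, 5L), collapse = ", "))
    }
    align_partition(g, graph)  # errors if any graph node missing
  }
  g
}

#' @rdname read_partition
#' @param g a partition.
#' @export
write_partition <- function(g, path) {
  writeLines(paste(names(g), unclass(g), sep = "\t"), path)
  invisible(path)
}

#' Block-level sufficient statistics
#'
#' Computes everything the block-model likelihoods need from a graph and a
#' partition: the edge-endpoint count matrix `m_rs` (with `m_rr` twice the
#' number of edges inside block `r`), block degree sums `kappa_r`, block
#' sizes `n_r`, and per-node internal/external degrees `k_plus`/`k_minus`.
#' Self-loops contribute entirely to `k_plus` and to the diagonal of `m_rs`.
#'
#' @param G a [multigraph()].
#' @param g a partition covering all nodes of `G`.
#' @param B number of blocks (defaults to the partition's).
#' @return A list of class `"block_summary"` with elements `m` (B x B),
#'   `kappa`, `n_r`, `k_plus`, `k_minus`, `B`, `m_total`.
#' @export
block_summary <- function(G, g, B = NULL) {
  stopifnot(inherits(G, "multigraph"))
  if (is.null(B)) B <- n_blocks(g)
  gv <- align_partition(g, G)
  if (any(gv > B)) stop("partition labels exceed B")

  r <- gv[G$ei]
  s <- gv[G$ej]
  w <- G$mult
  same <- r == s
  loop <- G$ei == G$ej

  m <- matrix(0, B, B)
  pos <- c((s[!same] - 1L) * B + r[!same],
           (r[!same] - 1L) * B + s[!same],
           (r[same] - 1L) * B + r[same])
  val <- c(w[!same], w[!same], 2 * w[same])
  if (length(pos)) {
    agg <- rowsum(val, pos)
    m[as.integer(rownames(agg))] <- agg[, 1L]
  }

  k_plus <- numeric(G$n)
  in_same <- same & !loop
  if (any(in_same)) {
    k_plus <- k_plus + tab_sum(G$ei[in_same], w[in_same], G$n) +
      tab_sum(G$ej[in_same], w[in_same], G$n)
  }
  if (any(loop)) {
    k_plus <- k_plus + tab_sum(G$ei[loop], 2 * w[loop], G$n)
  }

  kappa <- numeric(B)
  aggk <- rowsum(as.numeric(G$deg), gv)
  kappa[as.integer(rownames(aggk))] <- aggk[, 1L]

  structure(
    list(m = m, kappa = kappa, n_r = tabulate(gv, B),
         k_plus = stats::setNames(k_plus, G$nodes),
         k_minus = stats::setNames(as.numeric(G$deg) - k_plus, G$nodes),
         B = B, m_total = G$m),
    class = "block_summary"
  )
}

#' @export
print.block_summary <- function(x, ...) {
  cat(sprintf("Block summary: B = %d, 2m = %g\n", x$B, sum(x$m)))
  cat("m_rs:\n")
  print(x$m)
  cat("kappa_r:", x$kappa, "\n")
  cat("n_r:    ", x$n_r, "\n")
  invisible(x)
}
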
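#' Construct an undirected multigraph
#'
#' Builds the package's multigraph representation from parallel vectors of
#' edge endpoints. Repeated endpoint pairs accumulate multiplicity, and a
#' self-loop at node `i` contributes 2 to the diagonal adjacency entry
#' (`A_ii = 2k` for `k` self-loops) and 2 to the degree of `i`, the standard
#' convention for Poisson multigraph block models.
#'
#' @param from,to character (or coercible) vectors of edge endpoints; each
#'   position is one edge instance unless `mult` is given.
#' @param mult optional non-negative integer multiplicities, one per
#'   `(from, to)` pair.
#' @param nodes optional character vector fixing the node set and its order;
#'   defaults to first-appearance order. May include isolated nodes.
#' @return An object of class `"multigraph"`: a list with elements `nodes`
#'   (identifiers), `n` (node count), `ei`, `ej` (1-based endpoint indices
#'   with `ei <= ej`), `mult` (edge multiplicities), `deg` (degree sequence,
#'   self-loops counting 2), and `m` (total edge instances, self-loops
#'   counting 1).
#' @examples
#' g <- multigraph(c("a", "b", "a"), c("b", "c", "b"))
#' g$deg  # a:2 b:3 c:1
#' @export
multigraph <- function(from, to, mult = NULL, nodes = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) {
    stop("'from' and 'to' must have equal length")
  }
  if (length(from) == 0L) stop("a multigraph must contain at least one edge")
  if (is.null(mult)) {
    mult <- rep(1, length(from))
  } else {
    mult <- as.numeric(mult)
    if (length(mult) != length(from)) stop("'mult' length mismatch")
    if (any(mult < 0) || any(mult != round(mult))) {
      stop("edge multiplicities must be non-negative integers")
    }
  }
  keep <- mult > 0
  from <- from[keep]; to <- to[keep]; mult <- mult[keep]
  if (length(from) == 0L) stop("a multigraph must contain at least one edge")

  if (is.null(nodes)) {
    nodes <- unique(as.vector(rbind(from, to)))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node identifiers in 'nodes'")
    unknown <- setdiff(unique(c(from, to)), nodes)
    if (length(unknown)) {
      stop("edge endpoints not in 'nodes': ", paste(unknown, collapse = ", "))
    }
  }
  i <- match(from, nodes)
  j <- match(to, nodes)
  lo <- pmin(i, j)
  hi <- pmax(i, j)

  key <- paste(lo, hi, sep = "_")
  first <- !duplicated(key)
  uk <- key[first]
  agg <- rowsum(mult, key)
  w <- as.numeric(agg[match(uk, rownames(agg)), 1L])
  ei <- lo[first]
  ej <- hi[first]

  n <- length(nodes)
  deg <- numeric(n)
  loop <- ei == ej
  if (any(!loop)) {
    deg <- deg + tab_sum(ei[!loop], w[!loop], n) + tab_sum(ej[!loop], w[!loop], n)
  }
  if (any(loop)) {
    deg <- deg + tab_sum(ei[loop], 2 * w[loop], n)
  }

  structure(
    list(nodes = nodes, n = n, ei = ei, ej = ej, mult = w,
         deg = stats::setNames(deg, nodes), m = sum(w)),
    class = "multigraph"
  )
}

# weighted tabulate: sum w by index over 1..n
tab_sum <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' @export
print.multigraph <- function(x, ...) {
  cat(sprintf("Undirected multigraph: %d nodes, %g edges (%d distinct pairs)\n",
              x$n, x$m, length(x$mult)))
  nl <- sum(x$mult[x$ei == x$ej])
  if (nl > 0) cat(sprintf("  self-loops: %g\n", nl))
  cat(sprintf("  degree range: [%g, %g]\n", min(x$deg), max(x$deg)))
  invisible(x)
}

#' Coerce to a multigraph
#'
#' @param x an object: an igraph graph, a two-column matrix or a data frame
#'   whose first two columns are edge endpoints.
#' @param ... passed to methods.
#' @return A [multigraph()] object.
#' @export
as_multigraph <- function(x, ...) UseMethod("as_multigraph")

#' @export
as_multigraph.multigraph <- function(x, ...) x

#' @rdname as_multigraph
#' @param weights how to treat edge weights if present: `"ignore"` (each edge
#'   counts once) or `"multiplicity"` (weights rounded to integer
#'   multiplicities).
#' @export
as_multigraph.igraph <- function(x, weights = c("ignore", "multiplicity"), ...) {
  weights <- match.arg(weights)
  if (igraph::is_directed(x)) stop("only undirected graphs are supported")
  el <- igraph::as_edgelist(x, names = TRUE)
  el <- matrix(as.character(el), ncol = 2L)
  mult <- NULL
  if (weights == "multiplicity" && "weight" %in% igraph::edge_attr_names(x)) {
    mult <- round(igraph::E(x)$weight)
  }
  multigraph(el[, 1L], el[, 2L], mult = mult,
             nodes = as.character(igraph::V(x)$name %||% seq_len(igraph::vcount(x))))
}

#' @export
as_multigraph.matrix <- function(x, ...) multigraph(x[, 1L], x[, 2L])

#' @export
as_multigraph.data.frame <- function(x, ...) multigraph(x[[1L]], x[[2L]])

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an edge list file
#'
#' Parses a whitespace-separated edge-list file into a multigraph. Lines are
#' `source target [weight]`; everything after `#` is a comment. Repeated
#' lines accumulate edge multiplicity; a line `a a` is one self-loop
#' (diagonal adjacency 2).
#'
#' @param path path to the edge-list file.
#' @param weights `"ignore"` (default; a third column, if any, is skipped) or
#'   `"multiplicity"` (third column rounded to an integer multiplicity).
#' @return A [multigraph()].
#' @export
read_edge_list <- function(path, weights = c("ignore", "multiplicity")) {
  weights <- match.arg(weights)
  lines <- readLines(path, warn = FALSE)
  body <- sub("#.*$", "", lines)
  body <- trimws(body)
  idx <- which(nzchar(body))
  if (length(idx) == 0L) stop("no edges found in '", path, "'")
  toks <- strsplit(body[idx], "[ \t]+")
  nt <- lengths(toks)
  if (any(nt < 2L)) {
    bad <- idx[which(nt < 2L)[1L]]
    stop(sprintf("malformed edge line %d in '%s': need at least two fields", bad, path))
  }
  from <- vapply(toks, `[[`, "", 1L)
  to <- vapply(toks, `[[`, "", 2L)
  mult <- NULL
  if (weights == "multiplicity") {
    w <- vapply(toks, function(t) if (length(t) >= 3L) t[[3L]] else "1", "")
    wn <- suppressWarnings(as.numeric(w))
    if (anyNA(wn)) {
      bad <- idx[which(is.na(wn))[1L]]
      stop(sprintf("malformed weight on line %d in '%s'", bad, path))
    }
    mult <- round(wn)
  }
  multigraph(from, to, mult = mult)
}

#' Write an edge list file
#'
#' One line per edge instance (multi-edges repeated); self-loops written once
#' per loop. Inverse of [read_edge_list()] up to node ordering.
#'
#' @param G a [multigraph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(G, path) {
  stopifnot(inherits(G, "multigraph"))
  rep_idx <- rep.int(seq_along(G$mult), G$mult)
  lines <- paste(G$nodes[G$ei[rep_idx]], G$nodes[G$ej[rep_idx]])
  writeLines(lines, path)
  invisible(path)
}

#' Read a GraphML file
#'
#' Thin wrapper over [igraph::read_graph()] keeping multi-edges and
#' self-loops as stored in the file.
#'
#' @inheritParams read_edge_list
#' @return A [multigraph()].
#' @export
read_graphml <- function(path, weights = c("ignore", "multiplicity")) {
  weights <- match.arg(weights)
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "each")
  as_multigraph(g, weights = weights)
}

#' Connected components of a multigraph
#'
#' Breadth-first search over the undirected edge structure (self-loops and
#' multiplicities do not affect connectivity).
#'
#' @param G a [multigraph()].
#' @return A list with `membership` (named integer vector of component ids,
#'   numbered by first appearance) and `sizes` (nodes per component).
#' @export
graph_components <- function(G) {
  stopifnot(inherits(G, "multigraph"))
  adj <- vector("list", G$n)
  for (e in seq_along(G$mult)) {
    i <- G$ei[e]; j <- G$ej[e]
    if (i != j) {
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  comp <- integer(G$n)
  cur <- 0L
  for (start in seq_len(G$n)) {
    if (comp[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (u in adj[[v]]) {
        if (comp[u] == 0L) {
          comp[u] <- cur
          queue <- c(queue, u)
        }
      }
    }
  }
  list(membership = stats::setNames(comp, G$nodes),
       sizes = tabulate(comp, cur))
}

#' Randomly remove edge instances
#'
#' Removes `floor(fraction * m)` edge instances (units of multiplicity)
#' chosen uniformly without replacement, used to sparsify a network while
#' keeping its node set. Nodes left isolated stay in the graph.
#'
#' @param G a [multigraph()].
#' @param fraction fraction of edge instances to remove, in `[0, 1)`.
#' @param seed optional integer seed for reproducibility.
#' @return A [multigraph()] on the same node set.
#' @export
remove_random_edges <- function(G, fraction, seed = NULL) {
  stopifnot(inherits(G, "multigraph"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction >= 1) {
    stop("'fraction' must be a single number in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  n_remove <- floor(fraction * G$m)
  if (n_remove == 0L) return(G)
  inst <- rep.int(seq_along(G$mult), G$mult)
  drop <- sample(seq_along(inst), n_remove)
  kept <- inst[-drop]
  if (length(kept) == 0L) stop("edge removal would empty the graph")
  tab <- table(kept)
  idx <- as.integer(names(tab))
  multigraph(G$nodes[G$ei[idx]], G$nodes[G$ej[idx]],
             mult = as.integer(tab), nodes = G$nodes)
}
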
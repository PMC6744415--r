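#' Planted-partition mixing matrix
#'
#' The assortative planted-partition form: within-block rate `gamma * omega0`
#' on the diagonal, between-block rate `omega0` off it. `gamma > 1` plants
#' assortative structure (stronger as `gamma` grows), `gamma < 1` plants
#' disassortative structure, `gamma = 1` none.
#'
#' @param B number of blocks (>= 2).
#' @param gamma within/between rate ratio, > 0.
#' @param omega0 between-block rate, > 0 (controls sparsity).
#' @return A `B x B` matrix.
#' @examples
#' planted_omega(2, gamma = 10, omega0 = 0.01)
#' @export
planted_omega <- function(B, gamma, omega0) {
  stopifnot(B >= 2, gamma > 0, omega0 >= 0)
  om <- matrix(omega0, B, B)
  diag(om) <- gamma * omega0
  om
}

#' Sample a discrete power-law degree sequence
#'
#' I.i.d. draws from `P(k)` proportional to `k^(-exponent)` on the integer
#' range `[k_min, k_max]`, by inverse-CDF on the exactly normalized mass
#' function (no continuous approximation).
#'
#' @param n number of draws.
#' @param exponent power-law exponent (> 1; 2.5 is the benchmark value).
#' @param k_min,k_max integer support bounds.
#' @param seed optional integer seed.
#' @return Integer vector of length `n`.
#' @export
sample_degree_sequence <- function(n, exponent = 2.5, k_min = 1, k_max = NULL,
                                   seed = NULL) {
  stopifnot(n >= 1, exponent > 1, k_min >= 1)
  if (is.null(k_max)) k_max <- max(k_min, n - 1L)
  if (k_min > k_max) stop("k_min must not exceed k_max")
  if (!is.null(seed)) set.seed(seed)
  ks <- k_min:k_max
  if (length(ks) == 1L) return(rep.int(as.integer(ks), n))
  p <- ks^(-exponent)
  sample(ks, n, replace = TRUE, prob = p / sum(p))
}

#' Sample a degree-corrected planted-partition benchmark graph
#'
#' Generates a Poisson multigraph from the degree-corrected stochastic block
#' model with planted-partition mixing: target degrees are drawn from a
#' discrete power law, nodes are randomly assigned to blocks of the given
#' sizes, and edge counts are Poisson with mean
#' `lambda_ij = omega[g_i, g_j] * k_i * k_j` for `i < j` and self-loop
#' counts Poisson with mean `lambda_ii / 2` (stored as diagonal adjacency
#' `2k`). The defaults are the benchmark conditions used throughout:
#' two equal blocks of 10 nodes, exponent 2.5, `omega0 = 0.01`,
#' `gamma = 10`.
#'
#' @param n node count.
#' @param B block count.
#' @param block_sizes optional explicit sizes summing to `n` (default as
#'   equal as possible).
#' @param gamma,omega0 mixing parameters, see [planted_omega()].
#' @param exponent,k_min,k_max degree-sequence parameters, see
#'   [sample_degree_sequence()].
#' @param seed optional integer seed.
#' @param isolated what to do with nodes that draw no edges: `"drop"`
#'   (default, with a warning) or `"keep"`.
#' @return A list with `graph` (a [multigraph()]), `partition` (the planted
#'   truth, restricted to retained nodes), `omega` (the mixing matrix) and
#'   `target_degrees`.
#' @export
sample_dcsbm <- function(n = 20, B = 2, block_sizes = NULL, gamma = 10,
                         omega0 = 0.01, exponent = 2.5, k_min = 1,
                         k_max = NULL, seed = NULL,
                         isolated = c("drop", "keep")) {
  isolated <- match.arg(isolated)
  if (is.null(block_sizes)) {
    block_sizes <- rep(n %/% B, B) + c(rep(1L, n %% B), rep(0L, B - n %% B))
  }
  stopifnot(sum(block_sizes) == n, length(block_sizes) == B)
  if (!is.null(seed)) set.seed(seed)

  k <- sample_degree_sequence(n, exponent = exponent, k_min = k_min,
                              k_max = k_max)
  g <- sample(rep.int(seq_len(B), block_sizes))  # random assignment to blocks
  om <- planted_omega(B, gamma, omega0)

  nodes <- paste0("v", seq_len(n))
  lam <- om[g, g] * outer(k, k)

  up <- which(upper.tri(lam), arr.ind = TRUE)
  a_up <- stats::rpois(nrow(up), lam[up])
  loops <- stats::rpois(n, diag(lam) / 2)

  from <- c(nodes[up[, 1L]], nodes)
  to <- c(nodes[up[, 2L]], nodes)
  mult <- c(a_up, loops)
  if (sum(mult) == 0) stop("generated graph has no edges; increase omega0 or gamma")
  keep <- mult > 0
  G <- multigraph(from[keep], to[keep], mult = mult[keep], nodes = nodes)

  if (isolated == "drop" && any(G$deg == 0)) {
    iso <- nodes[G$deg == 0]
    warning(sprintf("dropping %d isolated node(s): %s", length(iso),
                    paste(utils::head(iso, 5L), collapse = ", ")))
    kept <- setdiff(nodes, iso)
    G <- multigraph(from[keep], to[keep], mult = mult[keep], nodes = kept)
    truth <- as_partition(stats::setNames(g[match(kept, nodes)], kept), B = B)
  } else {
    truth <- as_partition(stats::setNames(g, nodes), B = B)
  }

  list(graph = G, partition = truth, omega = om,
       target_degrees = stats::setNames(k, nodes))
}
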
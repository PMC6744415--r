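# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (double loops, direct formulas) so
# it cannot share a code path with the implementation it checks.

# Erdos-Renyi-ish random multigraph with optional multi-edges and self-loops
rand_graph <- function(n, p = 0.25, seed = 1, multi = TRUE, loops = TRUE) {
  set.seed(seed)
  from <- character(0); to <- character(0)
  nodes <- paste0("n", seq_len(n))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j && !loops) next
      pr <- if (i == j) p / 4 else p
      k <- stats::rbinom(1, if (multi) 3 else 1, pr)
      if (k > 0) {
        from <- c(from, rep(nodes[i], k))
        to <- c(to, rep(nodes[j], k))
      }
    }
  }
  if (!length(from)) return(rand_graph(n, min(1, p * 2), seed + 1, multi, loops))
  G <- multigraph(from, to, nodes = nodes)
  # the models require k_i >= 1: attach any isolated node to node 1
  iso <- G$nodes[G$deg == 0]
  if (length(iso)) {
    G <- multigraph(c(from, iso), c(to, rep(nodes[1], length(iso))),
                    nodes = nodes)
  }
  G
}

rand_partition <- function(G, B = 2, seed = 1) {
  set.seed(seed)
  repeat {
    g <- sample.int(B, G$n, replace = TRUE)
    if (length(unique(g)) == B) break
  }
  as_partition(stats::setNames(g, G$nodes), B = B)
}

# brute-force block summary: double loop over all node pairs
brute_summary <- function(G, g) {
  B <- n_blocks(g)
  gv <- unclass(g)[G$nodes]
  A <- matrix(0, G$n, G$n)
  for (e in seq_along(G$mult)) {
    i <- G$ei[e]; j <- G$ej[e]
    if (i == j) A[i, i] <- A[i, i] + 2 * G$mult[e]
    else { A[i, j] <- A[i, j] + G$mult[e]; A[j, i] <- A[j, i] + G$mult[e] }
  }
  m <- matrix(0, B, B)
  kplus <- numeric(G$n)
  for (i in seq_len(G$n)) for (j in seq_len(G$n)) {
    if (i == j) {
      m[gv[i], gv[i]] <- m[gv[i], gv[i]] + A[i, i]
      kplus[i] <- kplus[i] + A[i, i]
    } else {
      m[gv[i], gv[j]] <- m[gv[i], gv[j]] + A[i, j] / 2 + A[j, i] / 2
      if (gv[i] == gv[j]) kplus[i] <- kplus[i] + A[i, j]
    }
  }
  list(m = m, k_plus = kplus)
}

# independent degree-corrected SBM profile log-likelihood,
# sum_rs m_rs log(m_rs / (kappa_r kappa_s))
dcsbm_profile <- function(G, g) {
  bs <- block_summary(G, g)
  tot <- 0
  for (r in seq_len(bs$B)) for (s in seq_len(bs$B)) {
    if (bs$m[r, s] > 0) {
      tot <- tot + bs$m[r, s] * log(bs$m[r, s] / (bs$kappa[r] * bs$kappa[s]))
    }
  }
  tot
}

# brute-force Newman modularity via the full adjacency double loop
brute_modularity <- function(G, g) {
  gv <- unclass(g)[G$nodes]
  A <- matrix(0, G$n, G$n)
  for (e in seq_along(G$mult)) {
    i <- G$ei[e]; j <- G$ej[e]
    if (i == j) A[i, i] <- A[i, i] + 2 * G$mult[e]
    else { A[i, j] <- A[i, j] + G$mult[e]; A[j, i] <- A[j, i] + G$mult[e] }
  }
  k <- rowSums(A)
  m2 <- sum(k)
  q <- 0
  for (i in seq_len(G$n)) for (j in seq_len(G$n)) {
    if (gv[i] == gv[j]) q <- q + A[i, j] - k[i] * k[j] / m2
  }
  q / m2
}

# disjoint union of two complete graphs of the given sizes
two_cliques <- function(n1 = 5, n2 = 5) {
  from <- character(0); to <- character(0)
  for (i in 1:(n1 - 1)) for (j in (i + 1):n1) {
    from <- c(from, paste0("a", i)); to <- c(to, paste0("a", j))
  }
  for (i in 1:(n2 - 1)) for (j in (i + 1):n2) {
    from <- c(from, paste0("b", i)); to <- c(to, paste0("b", j))
  }
  multigraph(from, to)
}

clique_partition <- function(G) {
  as_partition(stats::setNames(ifelse(grepl("^a", G$nodes), 1L, 2L), G$nodes),
               B = 2)
}

# per-node constant prior (finite likelihood on every partition)
flat_prior <- function(G, f = 0.6) {
  prior_spec("rsbm_pernode",
             f_pernode = stats::setNames(rep(f, G$n), G$nodes))
}

karate_path <- function() {
  system.file("extdata", "karate.edgelist", package = "rsbm", mustWork = TRUE)
}
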
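#' Exact two-block maximum by exhaustive enumeration
#'
#' Enumerates every feasible assignment of the prior's constraint groups
#' (nodes forced together by zero outside rates, e.g. degree-one nodes with
#' `f_i = 1` and their anchors; singletons otherwise) to two blocks and
#' returns the global maximum of the profile log-likelihood. Enumeration
#' walks a Gray code so each state differs from the previous one by a
#' single group move and costs only an incremental update; one block label
#' is fixed by symmetry, so `2^(g - 1)` states are visited for `g` groups.
#' Practical up to roughly 22 groups; intended as the exact oracle for the
#' small benchmark graphs and for validating MCMC results.
#'
#' @inheritParams rsbm_loglik
#' @param forbid_empty skip assignments leaving a block empty (default
#'   `TRUE`).
#' @return A list with `partition` (the maximizing partition),
#'   `log_likelihood`, and `n_states` (number of assignments visited).
#' @export
exhaustive_search <- function(G, spec, forbid_empty = TRUE) {
  rp <- resolve_prior(spec, G)
  st <- make_state(G, rep(1L, G$n), rp, 2L)
  ng <- st$n_groups
  if (ng < 2L) stop("prior constraints force a single block")
  if (ng > 25L) stop("too many constraint groups (", ng, ") for enumeration")

  # start: all groups in block 1; walk the Gray code over groups 1..ng-1
  best_badw <- Inf
  best_fin <- -Inf
  best_g <- st$g
  consider <- function() {
    if (forbid_empty && any(st$nr == 0L)) return(invisible())
    fin <- state_mterm(st) + st$P
    if (st$Badw < best_badw ||
        (st$Badw == best_badw && fin > best_fin)) {
      best_badw <<- st$Badw
      best_fin <<- fin
      best_g <<- st$g
    }
    invisible()
  }
  consider()
  prev <- 0L
  for (i in seq_len(2L^(ng - 1L) - 1L)) {
    gray <- bitwXor(i, i %/% 2L)
    flip <- which(bitwAnd(bitwXor(gray, prev), 2L^(seq_len(ng - 1L) - 1L)) > 0L)
    prev <- gray
    members <- st$groups[[flip]]
    apply_group_move(st, members, 3L - st$g[members[1L]])
    consider()
  }
  if (!is.finite(best_fin) && !is.finite(best_badw)) {
    stop("no admissible two-block assignment found")
  }
  list(partition = as_partition(stats::setNames(best_g, G$nodes), B = 2L),
       log_likelihood = if (best_badw > 0) -Inf else best_fin,
       n_states = 2L^(ng - 1L))
}

#' Generate a convergence-benchmark instance
#'
#' Draws planted-partition benchmark graphs from [sample_dcsbm()] (defaults:
#' two blocks of 10 nodes, power-law degree exponent 2.5,
#' `omega0 = 0.01`, `gamma = 10`) with seeds `seed, seed + 1, ...` until one
#' satisfies the premises of the convergence experiment, which compares
#' MCMC restarts against the planted partition and therefore needs an
#' instance on which that comparison is meaningful:
#'
#' 1. all `n` nodes are retained (no isolated draws) and the graph is
#'    connected — a disconnected component can sit in either block, so no
#'    partition would be a unique optimum;
#' 2. the planted partition is feasible under the assortative floor prior:
#'    every degree-one node lies in its neighbour's block (the model's
#'    `f(1) = 1` premise — a degree-one node must connect to its own
#'    community);
#' 3. the planted partition is the global maximum of the floor-prior
#'    profile log-likelihood over all feasible bipartitions, verified
#'    exactly with [exhaustive_search()] — the experiment measures
#'    convergence *to* the planted optimum, so the planted partition must
#'    be the optimum.
#'
#' @param seed integer; first generator seed to try.
#' @param f floor of the assortative prior used in conditions 2-3.
#' @param max_tries give up after this many draws.
#' @param ... further arguments passed to [sample_dcsbm()].
#' @return As [sample_dcsbm()], plus `generator_seed` (the accepted seed)
#'   and `tries` (number of draws).
#' @export
benchmark_instance <- function(seed = 1, f = 0.8, max_tries = 2000, ...) {
  spec <- prior_spec("rsbm_floor", f = f)
  for (k in seq_len(max_tries)) {
    s <- seed + k - 1L
    b <- tryCatch(sample_dcsbm(seed = s, isolated = "keep", ...),
                  error = function(e) NULL)
    if (is.null(b)) next
    G <- b$graph
    if (any(G$deg == 0) || length(graph_components(G)$sizes) > 1L) next
    ll <- rsbm_loglik(G, b$partition, spec)$log_likelihood
    if (!is.finite(ll)) next
    ex <- exhaustive_search(G, spec)
    if (ll < ex$log_likelihood - 1e-9) next
    b$generator_seed <- s
    b$tries <- k
    return(b)
  }
  stop("no admissible benchmark instance found in ", max_tries, " draws")
}
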
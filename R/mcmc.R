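# Mutable chain state for single-node-move MCMC.
#
# The state keeps the sufficient statistics the profile likelihood needs so
# that one proposal costs O(B^2 + deg(v)): the m_rs matrix, per-block sums of
# I and O, per-node internal degrees, and the per-node likelihood terms
# 2(k+ log I + k- log O) held as a running sum. Moves are applied in place
# and reverted exactly (the reverse move recomputes identical floating-point
# terms), so rejection restores the state bit-for-bit.
#
# Infeasible states (some node with internal edges but I = 0, or external
# edges but O = 0; log-likelihood -Inf) are handled through a soft barrier:
# the chain's working objective is the finite likelihood part minus
# 2 * barrier per edge endpoint sitting on a zero-rate parameter (badw).
# The exact log-likelihood of such states is still reported as -Inf. A hard
# -Inf constraint freezes single-node chains: a random start with two
# misplaced degree-one nodes (f = 1 makes their external edges impossible)
# could never be repaired one move at a time, and a hub with a degree-one
# satellite could never change block at all. The finite barrier lets a
# decisively improving hub move temporarily strand its satellite, which
# then follows.

make_state <- function(G, gv, prior, B) {
  n <- G$n
  loop <- G$ei == G$ej
  nbr <- vector("list", n)
  nbw <- vector("list", n)
  if (any(!loop)) {
    ii <- c(G$ei[!loop], G$ej[!loop])
    jj <- c(G$ej[!loop], G$ei[!loop])
    ww <- c(G$mult[!loop], G$mult[!loop])
    ord <- order(ii)
    sp <- split(seq_along(ii)[ord], ii[ord])
    for (nm in names(sp)) {
      v <- as.integer(nm)
      nbr[[v]] <- jj[sp[[nm]]]
      nbw[[v]] <- ww[sp[[nm]]]
    }
  }
  for (v in seq_len(n)) {
    if (is.null(nbr[[v]])) { nbr[[v]] <- integer(0); nbw[[v]] <- numeric(0) }
  }
  loops2 <- numeric(n)  # A_ii = 2 * number of self-loops
  if (any(loop)) loops2 <- tab_sum(G$ei[loop], 2 * G$mult[loop], n)

  # constraint groups: a node with O = 0 (prior in-degree ratio 1, e.g. a
  # degree-one node under f(1) = 1) must share a block with every neighbour
  # in any finite-likelihood partition, so such nodes are merged with their
  # neighbours into groups that the sampler moves as units. Without zero
  # rates every group is a singleton and the chain is the plain
  # single-node-move sampler.
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (v in which(prior$O == 0)) {
    for (u in nbr[[v]]) {
      ru <- find(u); rv <- find(v)
      if (ru != rv) parent[ru] <- rv
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  groups <- unname(split(seq_len(n), root))

  st <- new.env(parent = emptyenv())
  st$groups <- groups
  st$n_groups <- length(groups)
  st$n <- n; st$B <- B
  st$deg <- as.numeric(G$deg)
  st$nbr <- nbr; st$nbw <- nbw; st$loops2 <- loops2
  st$I <- prior$I; st$O <- prior$O
  st$logI <- ifelse(prior$I > 0, log(prior$I), -Inf)
  st$logO <- ifelse(prior$O > 0, log(prior$O), -Inf)
  st$m2 <- 2 * G$m
  set_state_partition(st, gv)
  st
}

set_state_partition <- function(st, gv) {
  B <- st$B; n <- st$n
  st$g <- gv
  m <- matrix(0, B, B)
  kplus <- numeric(n)
  for (v in seq_len(n)) {
    a <- gv[v]
    nb <- st$nbr[[v]]; w <- st$nbw[[v]]
    if (length(nb)) {
      gb <- gv[nb]
      for (r in seq_len(B)) {
        dv <- sum(w[gb == r])
        if (dv > 0) m[a, r] <- m[a, r] + dv
      }
      kplus[v] <- sum(w[gb == a])
    }
    if (st$loops2[v] > 0) {
      m[a, a] <- m[a, a] + st$loops2[v]
      kplus[v] <- kplus[v] + st$loops2[v]
    }
  }
  st$m <- m
  st$kplus <- kplus
  st$nr <- tabulate(gv, B)
  SI <- numeric(B); SO <- numeric(B)
  aggI <- rowsum(st$I, gv); SI[as.integer(rownames(aggI))] <- aggI[, 1L]
  aggO <- rowsum(st$O, gv); SO[as.integer(rownames(aggO))] <- aggO[, 1L]
  st$SI <- SI; st$SO <- SO
  st$tval <- vapply(seq_len(n), function(v) node_term(st, v, kplus[v]), 0)
  st$badw <- vapply(seq_len(n), function(v) node_badw(st, v, kplus[v]), 0)
  st$P <- sum(st$tval)
  st$Badw <- sum(st$badw)
  invisible(st)
}

# finite part of the per-node likelihood term 2(k+ log I + k- log O):
# endpoints sitting on zero-rate parameters are excluded (tracked by badw)
node_term <- function(st, v, kp) {
  km <- st$deg[v] - kp
  t <- 0
  if (kp > 0 && st$I[v] > 0) t <- t + kp * st$logI[v]
  if (km > 0 && st$O[v] > 0) t <- t + km * st$logO[v]
  2 * t
}

# edge-endpoint weight on zero-rate parameters (0 iff the node's term is finite)
node_badw <- function(st, v, kp) {
  km <- st$deg[v] - kp
  (if (st$I[v] == 0) kp else 0) + (if (st$O[v] == 0) km else 0)
}

# block-pair term; entries whose Lambda vanishes (possible only in
# infeasible states) are skipped — they are accounted for by Badw
state_mterm <- function(st) {
  B <- st$B
  m <- st$m
  mterm <- 0
  for (r in seq_len(B)) {
    if (m[r, r] > 0 && st$SI[r] > 0) {
      mterm <- mterm + m[r, r] * log(m[r, r] / st$SI[r]^2)
    }
    if (r < B) for (s in (r + 1L):B) {
      if (m[r, s] > 0 && st$SO[r] > 0 && st$SO[s] > 0) {
        mterm <- mterm + 2 * m[r, s] * log(m[r, s] / (st$SO[r] * st$SO[s]))
      }
    }
  }
  mterm
}

state_loglik <- function(st) {
  if (st$Badw > 0) return(-Inf)
  state_mterm(st) + st$P
}

# working objective: finite likelihood part with the soft infeasibility
# barrier (equals the exact log-likelihood whenever the state is feasible)
state_objective <- function(st, barrier) {
  state_mterm(st) + st$P - 2 * barrier * st$Badw
}

state_coverage <- function(st) sum(diag(st$m)) / st$m2

# move node v to block b, updating all sufficient statistics in place
apply_move <- function(st, v, b) {
  a <- st$g[v]
  if (a == b) return(invisible(st))
  B <- st$B
  nb <- st$nbr[[v]]; w <- st$nbw[[v]]
  d <- numeric(B)
  gb <- integer(0)
  if (length(nb)) {
    gb <- st$g[nb]
    agg <- rowsum(w, gb)
    d[as.integer(rownames(agg))] <- agg[, 1L]
  }
  Aii <- st$loops2[v]

  st$m[a, ] <- st$m[a, ] - d
  st$m[, a] <- st$m[, a] - d
  st$m[a, a] <- st$m[a, a] - Aii
  st$m[b, ] <- st$m[b, ] + d
  st$m[, b] <- st$m[, b] + d
  st$m[b, b] <- st$m[b, b] + Aii

  upd <- function(u, kp_new) {
    st$P <- st$P - st$tval[u]
    st$Badw <- st$Badw - st$badw[u]
    st$tval[u] <- node_term(st, u, kp_new)
    st$badw[u] <- node_badw(st, u, kp_new)
    st$kplus[u] <- kp_new
    st$P <- st$P + st$tval[u]
    st$Badw <- st$Badw + st$badw[u]
  }
  upd(v, d[b] + Aii)
  if (length(nb)) {
    for (t in seq_along(nb)) {
      u <- nb[t]
      if (gb[t] == a) upd(u, st$kplus[u] - w[t])
      else if (gb[t] == b) upd(u, st$kplus[u] + w[t])
    }
  }

  st$SI[a] <- st$SI[a] - st$I[v]; st$SI[b] <- st$SI[b] + st$I[v]
  st$SO[a] <- st$SO[a] - st$O[v]; st$SO[b] <- st$SO[b] + st$O[v]
  st$nr[a] <- st$nr[a] - 1L; st$nr[b] <- st$nr[b] + 1L
  st$g[v] <- b
  invisible(st)
}

# move all members of a constraint group to block b; returns previous
# blocks for exact reversal
apply_group_move <- function(st, members, b) {
  old <- st$g[members]
  for (v in members) if (st$g[v] != b) apply_move(st, v, b)
  old
}

revert_group_move <- function(st, members, old) {
  for (t in rev(seq_along(members))) {
    if (st$g[members[t]] != old[t]) apply_move(st, members[t], old[t])
  }
}

#' Log-likelihood change of a single-node move
#'
#' Computes `log_likelihood(after) - log_likelihood(before)` for moving one
#' node to another block, using the incremental bookkeeping the sampler
#' relies on (only the affected rows/columns of `m_rs` and the moved node's
#' neighbourhood are touched). Agrees with a full recomputation to well
#' below `1e-8`.
#'
#' @inheritParams rsbm_loglik
#' @param node node identifier (or index).
#' @param new_block target block in `1..B`.
#' @return A single number; `-Inf`/`Inf` when the move enters/leaves an
#'   impossible configuration.
#' @export
delta_log_likelihood <- function(G, g, spec, node, new_block, B = NULL) {
  rp <- resolve_prior(spec, G)
  if (is.null(B)) B <- n_blocks(g)
  gv <- align_partition(g, G)
  v <- if (is.character(node)) match(node, G$nodes) else as.integer(node)
  if (is.na(v) || v < 1L || v > G$n) stop("unknown node")
  if (new_block < 1L || new_block > B) stop("invalid target block")
  st <- make_state(G, gv, rp, B)
  ll0 <- state_loglik(st)
  apply_move(st, v, as.integer(new_block))
  ll1 <- state_loglik(st)
  dll(ll1, ll0)
}

# difference with -Inf semantics: (-Inf) - (-Inf) := 0 (move between two
# impossible states; treated as rejectable)
dll <- function(ll1, ll0) {
  if (is.infinite(ll1) && is.infinite(ll0)) return(if (ll1 == ll0) 0 else ll1 - ll0)
  ll1 - ll0
}

#' Single-chain MCMC over partitions
#'
#' Metropolis sampling (or greedy ascent) over node partitions with uniform
#' single-node proposals: a node is drawn uniformly, a new block uniformly
#' among the other `B - 1`; proposals that would empty a block are redrawn
#' when `forbid_empty = TRUE` (the number of blocks is fixed throughout). In
#' `"sample"` mode a move is accepted with probability
#' `min(1, exp(delta))`; in `"greedy"` mode only strictly improving moves
#' are accepted, so each chain converges to a local maximum of the profile
#' log-likelihood. `-Inf` likelihoods are handled explicitly: any finite
#' state beats them and moves between impossible states are rejected.
#'
#' @param G a [multigraph()].
#' @param spec a [prior_spec()] or resolved prior.
#' @param B number of blocks.
#' @param steps number of proposals.
#' @param seed integer seed (set once at chain start; `NULL` to use the
#'   current RNG state).
#' @param mode `"greedy"` (default) or `"sample"`.
#' @param init optional starting [as_partition()]; default a uniform random
#'   partition with no empty block.
#' @param forbid_empty keep every block non-empty (default `TRUE`).
#' @param record_every record the trace every this many steps.
#' @param reference optional ground-truth partition; if given, the first
#'   step at which the chain state equals it (up to block-label permutation)
#'   is recorded.
#' @param barrier soft-barrier penalty, in log-likelihood units per edge
#'   endpoint, charged by the chain's working objective for each endpoint
#'   sitting on a zero-rate parameter (a node with external edges but
#'   `O_i = 0`, e.g. a degree-one node with `f_i = 1` placed against its
#'   only neighbour, or internal edges but `I_i = 0`). Such states have
#'   exact log-likelihood `-Inf`; the finite barrier keeps the single-node
#'   chain ergodic across them (see Details in the vignette). The default 3
#'   makes one impossible endpoint cost 6 log-likelihood units, large
#'   against ordinary single-move changes but crossable when a move is
#'   decisively favoured.
#' @param refine_steps optional greedy clean-up proposals appended after the
#'   main phase, so a sampling run ends in the local maximum of a basin.
#'   Step indices continue through the refinement.
#' @param refine_from where the refinement starts: `"final"` (default) keeps
#'   the chain's final state, so the trial reports the basin it converged
#'   to; `"best"` restarts from the best state visited, turning the run
#'   into a pure optimizer.
#' @return An object of class `"mcmc_trace"`: list with `partition` (the
#'   trial's result — the refined final state when refinement from the
#'   final state was run, else the best state visited) and its
#'   `log_likelihood`; `records` (data frame `step`, `log_likelihood`,
#'   `coverage`); `best_partition` and `best_log_likelihood` (best state
#'   visited, judged feasibility-first); `converged_step` (step at which
#'   the best state was first reached; 0 for the start state);
#'   `first_match_step` (first step whose state equals `reference` up to
#'   label permutation; `NA` if no reference or never matched);
#'   `final_partition`; `acceptance_rate`; `mode`; `seed`.
#' @export
mcmc_run <- function(G, spec, B = 2, steps = 2000, seed = NULL,
                     mode = c("greedy", "sample"), init = NULL,
                     forbid_empty = TRUE, record_every = 10,
                     reference = NULL, barrier = 3, refine_steps = 0,
                     refine_from = c("final", "best")) {
  stopifnot(is.numeric(barrier), length(barrier) == 1L, barrier > 0,
            refine_steps >= 0)
  refine_steps <- as.integer(refine_steps)
  refine_from <- match.arg(refine_from)
  mode <- match.arg(mode)
  stopifnot(inherits(G, "multigraph"), steps >= 1, B >= 2, record_every >= 1)
  if (G$n <= B && forbid_empty) stop("need more nodes than blocks")
  rp <- resolve_prior(spec, G)
  if (!is.null(seed)) set.seed(seed)
  ref_canon <- if (!is.null(reference)) canonical_labels(align_partition(reference, G))

  st <- make_state(G, rep(1L, G$n), rp, B)
  if (st$n_groups < B) {
    stop("prior constraints leave fewer movable groups than blocks")
  }
  if (is.null(init)) {
    # uniform random assignment of constraint groups to blocks (every
    # feasible partition assigns each group to a single block)
    repeat {
      gg <- sample.int(B, st$n_groups, replace = TRUE)
      if (length(unique(gg)) == B) break
    }
    gv <- integer(G$n)
    for (k in seq_len(st$n_groups)) gv[st$groups[[k]]] <- gg[k]
  } else {
    gv <- align_partition(init, G)
    if (max(gv) > B) stop("init partition has more than B blocks")
  }
  set_state_partition(st, as.integer(gv))
  obj <- state_objective(st, barrier)
  ll <- state_loglik(st)
  n <- st$n

  # best-so-far is judged feasibility-first (fewer impossible endpoints,
  # then higher finite likelihood part), independent of the barrier value
  best_g <- st$g
  best_badw <- st$Badw
  best_fin <- obj + 2 * barrier * st$Badw
  best_ll <- ll
  best_step <- 0L
  first_match <- NA_integer_
  if (!is.null(ref_canon) && identical(canonical_labels(st$g), ref_canon)) {
    first_match <- 0L
  }

  total <- steps + refine_steps
  nrec <- floor(total / record_every) + 2L
  rec_step <- integer(nrec); rec_ll <- numeric(nrec); rec_cov <- numeric(nrec)
  rec_step[1L] <- 0L; rec_ll[1L] <- ll; rec_cov[1L] <- state_coverage(st)
  ri <- 1L
  accepted <- 0L

  run_phase <- function(phase_mode, from, to) {
    for (step in from:to) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > 10000L) stop("no admissible move proposal found")
        k <- sample.int(st$n_groups, 1L)
        members <- st$groups[[k]]
        a <- st$g[members[1L]]
        bb <- sample.int(B - 1L, 1L)
        b <- if (bb >= a) bb + 1L else bb
        if (!forbid_empty) break
        newnr <- st$nr - tabulate(st$g[members], B)
        newnr[b] <- newnr[b] + length(members)
        if (all(newnr >= 1L)) break
      }
      old <- apply_group_move(st, members, b)
      obj_new <- state_objective(st, barrier)
      acc <- if (phase_mode == "greedy") {
        obj_new > obj
      } else {
        obj_new >= obj || stats::runif(1L) < exp(obj_new - obj)
      }
      if (acc) {
        accepted <<- accepted + 1L
        obj <<- obj_new
        ll <<- state_loglik(st)
        fin <- obj_new + 2 * barrier * st$Badw
        if (st$Badw < best_badw ||
            (st$Badw == best_badw && fin > best_fin)) {
          best_badw <<- st$Badw
          best_fin <<- fin
          best_ll <<- ll
          best_g <<- st$g
          best_step <<- step
        }
        if (!is.null(ref_canon) && is.na(first_match) &&
            identical(canonical_labels(st$g), ref_canon)) {
          first_match <<- step
        }
      } else {
        revert_group_move(st, members, old)
      }
      if (step %% record_every == 0L) {
        ri <<- ri + 1L
        rec_step[ri] <<- step; rec_ll[ri] <<- ll; rec_cov[ri] <<- state_coverage(st)
      }
    }
  }

  run_phase(mode, 1L, steps)
  if (refine_steps > 0L) {
    if (refine_from == "best" && !identical(st$g, best_g)) {
      set_state_partition(st, best_g)
      obj <- state_objective(st, barrier)
      ll <- state_loglik(st)
    }
    run_phase("greedy", steps + 1L, total)
  }

  final_part <- as_partition(stats::setNames(st$g, G$nodes), B = B)
  best_part <- as_partition(stats::setNames(best_g, G$nodes), B = B)
  # the trial's result: the state the chain converged to (refined final
  # state) when a final-state refinement was run, otherwise the best state
  # visited
  use_final <- refine_steps > 0L && refine_from == "final"
  structure(
    list(partition = if (use_final) final_part else best_part,
         log_likelihood = if (use_final) state_loglik(st) else best_ll,
         records = data.frame(step = rec_step[1:ri], log_likelihood = rec_ll[1:ri],
                              coverage = rec_cov[1:ri]),
         best_partition = best_part,
         best_log_likelihood = best_ll,
         converged_step = best_step,
         first_match_step = first_match,
         final_partition = final_part,
         acceptance_rate = accepted / total,
         mode = mode, seed = seed),
    class = "mcmc_trace"
  )
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat(sprintf("MCMC trace (%s mode): best log-likelihood %g at step %d, acceptance %.1f%%\n",
              x$mode, x$best_log_likelihood, x$converged_step,
              100 * x$acceptance_rate))
  invisible(x)
}

#' Independent MCMC restarts
#'
#' Runs `restarts` independent chains with seeds `seed, seed + 1, ...`, each
#' from a fresh uniform-random partition, and optionally counts how many
#' best partitions match a reference up to block-label permutation.
#'
#' @inheritParams mcmc_run
#' @param restarts number of trials.
#' @param ... further arguments passed to [mcmc_run()].
#' @return A list with `traces` (list of [mcmc_run()] traces) and
#'   `n_matched` (`NA` if no reference was supplied).
#' @export
multi_restart <- function(G, spec, B = 2, restarts = 20, steps = 2000,
                          seed = 1, reference = NULL, ...) {
  stopifnot(restarts >= 1)
  traces <- lapply(seq_len(restarts) - 1L, function(k) {
    mcmc_run(G, spec, B = B, steps = steps, seed = seed + k,
             reference = reference, ...)
  })
  n_matched <- NA_integer_
  if (!is.null(reference)) {
    n_matched <- sum(vapply(traces, function(tr) {
      match_partitions(tr$partition, reference)$matches_reference
    }, FALSE))
  }
  list(traces = traces, n_matched = n_matched)
}

#' Warm-started sweep over the prior in-degree-ratio floor
#'
#' Runs one chain per value of an increasing grid of floors `f`, with the
#' prior `f_i = max(f, 1/k_i)` and `theta_i = k_i`. The first chain starts
#' from a uniform-random partition; every later chain starts from the
#' previous one's best partition, tracing how the inferred structure changes
#' from disassortative to assortative as `f` grows.
#'
#' @inheritParams mcmc_run
#' @param f_grid strictly increasing values in (0, 1).
#' @param ... further arguments passed to [mcmc_run()].
#' @return A list with `table` (data frame `f`, `log_likelihood`,
#'   `coverage`, `modularity`) and `partitions` (list of the partitions the
#'   chain converged to, one per grid value).
#' @export
f_sweep <- function(G, f_grid, B = 2, steps = 2000, seed = 1,
                    mode = "sample", record_every = 50, refine_steps = 500,
                    ...) {
  if (length(f_grid) < 1L || any(diff(f_grid) <= 0)) {
    stop("'f_grid' must be strictly increasing")
  }
  if (any(f_grid <= 0) || any(f_grid >= 1)) stop("'f_grid' values must lie in (0, 1)")
  init <- NULL
  parts <- vector("list", length(f_grid))
  out <- data.frame(f = f_grid, log_likelihood = NA_real_,
                    coverage = NA_real_, modularity = NA_real_)
  for (t in seq_along(f_grid)) {
    spec <- prior_spec("rsbm_floor", f = f_grid[t])
    tr <- mcmc_run(G, spec, B = B, steps = steps,
                   seed = if (t == 1L) seed else NULL,
                   mode = mode, init = init, record_every = record_every,
                   refine_steps = refine_steps, ...)
    parts[[t]] <- tr$partition
    init <- tr$partition
    out$log_likelihood[t] <- tr$log_likelihood
    out$coverage[t] <- coverage(G, tr$partition)
    out$modularity[t] <- modularity_score(G, tr$partition)
  }
  list(table = out, partitions = parts)
}
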
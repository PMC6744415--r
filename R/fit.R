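#' Fit a (regularized) stochastic block model by MCMC
#'
#' The front-door fitting function: infers a `B`-block partition of an
#' undirected multigraph by multi-restart single-node-move MCMC over the
#' profile log-likelihood of the chosen model — the regularized model
#' (steered by the prior in-degree-ratio parameter), the degree-corrected
#' model, or the standard stochastic block model.
#'
#' With `model = "rsbm"` the prior in-degree ratio is
#' `f_i = max(f, 1/k_i)` (or `f_i = alpha + (1 - alpha)/k_i` when `alpha`
#' is given) with `theta_i = k_i`. Values of `f` close to 1 steer the
#' inference toward assortative communities; values close to 0 toward
#' disassortative (e.g. core-periphery) structure. `model = "dcsbm"` makes
#' decisions identical to the degree-corrected stochastic block model,
#' which is indifferent between the two structure types.
#'
#' @param graph a [multigraph()], or anything [as_multigraph()] accepts.
#' @param B number of blocks (fixed; not inferred).
#' @param model `"rsbm"`, `"dcsbm"` or `"ssbm"`; ignored when `prior` is
#'   given.
#' @param f floor of the prior in-degree ratio for `"rsbm"`, in (0, 1).
#' @param alpha optional: use the affine prior `alpha + (1 - alpha)/k`
#'   instead of the floor form.
#' @param prior optional explicit [prior_spec()] overriding `model`.
#' @param steps MCMC proposals per restart.
#' @param restarts number of independent chains (seeds `seed`, `seed + 1`,
#'   ...).
#' @param mode `"sample"` (default: Metropolis at unit temperature,
#'   followed by a greedy refinement of the final state, see
#'   `refine_steps`) or `"greedy"` (pure ascent to a local maximum).
#' @param refine_steps greedy clean-up proposals appended to each chain so
#'   every trial ends in a local maximum of its basin.
#' @param seed integer seed.
#' @param reference optional ground-truth partition; recovery statistics
#'   are then reported.
#' @param ... further arguments passed to [mcmc_run()].
#' @return An object of class `"rsbm"` with components `partition` (best
#'   over all restarts), `log_likelihood`, `omega_hat`, `coverage`,
#'   `modularity`, `trials` (per-restart traces), `n_matched`, `spec`,
#'   `graph`, `B`, `call`. Supports `print`, `summary`, `coef`, `logLik`,
#'   `plot`, `simulate` and `residuals`.
#' @examples
#' bench <- sample_dcsbm(seed = 1)
#' fit <- rsbm(bench$graph, B = 2, f = 0.8, restarts = 5, seed = 1,
#'             reference = bench$partition)
#' fit
#' @export
rsbm <- function(graph, B = 2, model = c("rsbm", "dcsbm", "ssbm"), f = 0.8,
                 alpha = NULL, prior = NULL, steps = 2000, restarts = 20,
                 mode = "sample", refine_steps = 500, seed = 1,
                 reference = NULL, ...) {
  model <- match.arg(model)
  G <- as_multigraph(graph)
  spec <- if (!is.null(prior)) {
    prior
  } else {
    switch(model,
      rsbm = if (is.null(alpha)) prior_spec("rsbm_floor", f = f)
             else prior_spec("rsbm_affine", alpha = alpha),
      dcsbm = prior_spec("degree_corrected"),
      ssbm = prior_spec("standard"))
  }
  mr <- multi_restart(G, spec, B = B, restarts = restarts, steps = steps,
                      refine_steps = refine_steps, seed = seed, mode = mode,
                      reference = reference, ...)
  lls <- vapply(mr$traces, `[[`, 0, "log_likelihood")
  best <- which.max(lls)
  part <- mr$traces[[best]]$partition
  ev <- rsbm_loglik(G, part, spec, B = B)

  structure(
    list(partition = part,
         log_likelihood = ev$log_likelihood,
         omega_hat = ev$omega_hat,
         coverage = coverage(G, part),
         modularity = modularity_score(G, part),
         trials = mr$traces,
         n_matched = mr$n_matched,
         reference = reference,
         spec = spec, graph = G, B = B,
         best_trial = best,
         call = match.call()),
    class = "rsbm"
  )
}

#' @export
print.rsbm <- function(x, ...) {
  cat("Stochastic block model fit (", length(x$trials), " MCMC restarts)\n", sep = "")
  print(x$spec)
  cat(sprintf("  blocks: %d (sizes: %s)\n", x$B,
              paste(tabulate(unclass(x$partition), x$B), collapse = ", ")))
  cat(sprintf("  log-likelihood: %.4f\n", x$log_likelihood))
  cat(sprintf("  coverage: %.4f, modularity: %.4f\n", x$coverage, x$modularity))
  if (!is.na(x$n_matched)) {
    cat(sprintf("  restarts matching reference: %d / %d\n",
                x$n_matched, length(x$trials)))
  }
  invisible(x)
}

#' @export
summary.rsbm <- function(object, ...) {
  tab <- data.frame(
    trial = seq_along(object$trials),
    log_likelihood = vapply(object$trials, `[[`, 0, "log_likelihood"),
    coverage = vapply(object$trials, function(tr) {
      coverage(object$graph, tr$partition)
    }, 0),
    converged_step = vapply(object$trials, `[[`, 0L, "converged_step"),
    first_match_step = vapply(object$trials, `[[`, NA_integer_, "first_match_step")
  )
  if (!is.null(object$reference)) {
    tab$matched <- vapply(object$trials, function(tr) {
      match_partitions(tr$partition, object$reference)$matches_reference
    }, FALSE)
  }
  structure(list(fit = object, trials = tab), class = "summary.rsbm")
}

#' @export
print.summary.rsbm <- function(x, ...) {
  print(x$fit)
  cat("\nPer-trial results:\n")
  print(x$trials, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
coef.rsbm <- function(object, ...) object$omega_hat

#' @export
logLik.rsbm <- function(object, ...) {
  structure(object$log_likelihood,
            df = object$B * (object$B + 1) / 2,
            nobs = object$graph$m, class = "logLik")
}

#' @export
plot.rsbm <- function(x, ...) {
  recs <- lapply(x$trials, `[[`, "records")
  finite <- unlist(lapply(recs, function(r) r$log_likelihood))
  finite <- finite[is.finite(finite)]
  if (!length(finite)) stop("no finite log-likelihood values to plot")
  ylim <- range(finite)
  plot(NA, xlim = c(0, max(vapply(recs, function(r) max(r$step), 0))),
       ylim = ylim, xlab = "MCMC step", ylab = "log-likelihood",
       main = "Convergence of MCMC restarts", ...)
  for (r in recs) {
    keep <- is.finite(r$log_likelihood)
    graphics::lines(r$step[keep], r$log_likelihood[keep],
                    col = grDevices::grey(0.2, alpha = 0.5))
  }
  invisible(x)
}

#' Simulate graphs from a fitted block model
#'
#' Draws Poisson multigraphs from the fitted rates
#' \eqn{\hat\lambda_{ij}} at the inferred partition (edge counts Poisson
#' with mean \eqn{\hat\lambda_{ij}}, self-loop counts with mean
#' \eqn{\hat\lambda_{ii}/2}).
#'
#' @param object an [rsbm()] fit.
#' @param nsim number of graphs.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` [multigraph()] objects.
#' @export
simulate.rsbm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lam <- lambda_matrix(object$graph, object$partition, object$spec, B = object$B)
  nodes <- object$graph$nodes
  n <- length(nodes)
  up <- which(upper.tri(lam), arr.ind = TRUE)
  lapply(seq_len(nsim), function(s) {
    a_up <- stats::rpois(nrow(up), lam[up])
    loops <- stats::rpois(n, diag(lam) / 2)
    mult <- c(a_up, loops)
    keep <- mult > 0
    if (!any(keep)) stop("simulated graph has no edges")
    multigraph(c(nodes[up[, 1L]], nodes)[keep],
               c(nodes[up[, 2L]], nodes)[keep],
               mult = mult[keep], nodes = nodes)
  })
}

#' Degree residuals of a fitted block model
#'
#' `k_i - sum_j lambda_hat_ij`: the gap between observed degrees and the
#' expected degrees under the fitted rates. Exactly zero (up to numerical
#' tolerance) when `theta` is at its maximum-likelihood value
#' ([fit_theta_mle()]); at the default operating point `theta_i = k_i` the
#' residuals are small but not identically zero unless `f_i = 1/2`.
#'
#' @param object an [rsbm()] fit.
#' @param ... unused.
#' @return Named numeric vector.
#' @export
residuals.rsbm <- function(object, ...) {
  lam <- lambda_matrix(object$graph, object$partition, object$spec, B = object$B)
  as.numeric(object$graph$deg) - rowSums(lam)
}
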
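#' Profile log-likelihood of the regularized stochastic block model
#'
#' Evaluates, for a graph, a partition and a prior specification, the profile
#' log-likelihood with the block-pair rates maximized out analytically:
#'
#' \deqn{L(A | g, I, O) = \sum_{rs} m_{rs} \log\frac{m_{rs}}{\Lambda_{rs}}
#'   + 2\sum_i (k_i^+ \log I_i + k_i^- \log O_i)}
#'
#' with \eqn{\Lambda_{rr} = (\sum_{i \in r} I_i)^2} and
#' \eqn{\Lambda_{rs} = \sum_{i \in r} O_i \sum_{j \in s} O_j} for
#' \eqn{r \ne s}, under the convention \eqn{0 \log 0 = 0}. Setting
#' `I_i = O_i = 1` recovers the standard SBM profile likelihood
#' (\eqn{\Lambda_{rs} = n_r n_s}) and `I_i = O_i = k_i` the degree-corrected
#' one (\eqn{\Lambda_{rs} = \kappa_r \kappa_s}) up to partition-independent
#' constants.
#'
#' The value is `-Inf` whenever some node has external edges but `O_i = 0`
#' (for instance a degree-one node with `f_i = 1` placed against its only
#' neighbour) or internal edges but `I_i = 0`.
#'
#' @param G a [multigraph()].
#' @param g a partition of the nodes of `G`.
#' @param spec a [prior_spec()] or resolved prior.
#' @param B number of blocks (defaults to the partition's).
#' @return A list of class `"rsbm_loglik"`: `log_likelihood`, `Lambda`,
#'   `omega_hat` (`m_rs / Lambda_rs`), `cross_entropy_sum`
#'   (\eqn{\sum_i k_i H(k_i^+/k_i, f_i)}), `kl_term` (the
#'   \eqn{\sum m \log(m/\Lambda)} block term, the component whose differences
#'   across partitions carry the KL-divergence part of the objective at
#'   `theta_i = k_i`), `summary` (the [block_summary()]) and `prior`.
#' @examples
#' g <- multigraph(c("a", "b", "c"), c("b", "c", "a"))
#' part <- as_partition(c(a = 1, b = 1, c = 1))
#' rsbm_loglik(g, part, prior_spec("degree_corrected"))$log_likelihood
#' @export
rsbm_loglik <- function(G, g, spec, B = NULL) {
  rp <- resolve_prior(spec, G)
  bs <- block_summary(G, g, B = B)
  B <- bs$B
  gv <- align_partition(g, G)

  SI <- numeric(B); SO <- numeric(B)
  aggI <- rowsum(rp$I, gv); SI[as.integer(rownames(aggI))] <- aggI[, 1L]
  aggO <- rowsum(rp$O, gv); SO[as.integer(rownames(aggO))] <- aggO[, 1L]

  Lambda <- outer(SO, SO)
  diag(Lambda) <- SI^2

  kp <- as.numeric(bs$k_plus)
  km <- as.numeric(bs$k_minus)
  bad <- (kp > 0 & rp$I == 0) | (km > 0 & rp$O == 0)
  pernode <- 2 * (xlog(kp, rp$I) + xlog(km, rp$O))

  mterm <- sum(xlogq(bs$m, Lambda))
  ll <- if (any(bad)) -Inf else mterm + sum(pernode)

  omega <- matrix(0, B, B)
  nz <- bs$m > 0
  omega[nz] <- bs$m[nz] / Lambda[nz]

  k <- rp$k
  ce <- sum(k * (-xlog(kp / k, rp$f) - xlog(km / k, 1 - rp$f)))

  structure(
    list(log_likelihood = ll, Lambda = Lambda, omega_hat = omega,
         cross_entropy_sum = ce, kl_term = mterm,
         summary = bs, prior = rp),
    class = "rsbm_loglik"
  )
}

#' @export
print.rsbm_loglik <- function(x, ...) {
  cat(sprintf("RSBM profile log-likelihood: %g\n", x$log_likelihood))
  invisible(x)
}

# a * log(b) with the 0 log 0 = 0 convention (a = 0 always contributes 0)
xlog <- function(a, b) {
  out <- numeric(length(a))
  nz <- a > 0
  out[nz] <- a[nz] * log(b[if (length(b) == 1L) 1L else nz])
  out
}

# a * log(a / b), 0 log 0 = 0; b may be 0 only where a is 0
xlogq <- function(a, b) {
  out <- numeric(length(a))
  nz <- a > 0
  out[nz] <- a[nz] * log(a[nz] / b[nz])
  out
}

#' Cross-entropy form of the RSBM log-likelihood
#'
#' The algebraically identical rewriting of the profile log-likelihood in
#' terms of the prior in-degree ratios:
#'
#' \deqn{L = \sum_{rs} m_{rs}\log\frac{m_{rs}}{\Lambda_{rs}}
#'   - 2\sum_i k_i H\!\left(\frac{k_i^+}{k_i}, f_i\right)
#'   + 2\sum_i k_i \log \theta_i}
#'
#' where \eqn{H(p, f) = -p\log f - (1-p)\log(1-f)} is the cross entropy
#' between the observed in-degree ratio \eqn{k_i^+/k_i} and the prior
#' \eqn{f_i}. Maximizing it drives observed in-degree ratios toward the
#' prior ones, which is the regularization mechanism.
#'
#' @inheritParams rsbm_loglik
#' @return A single number, equal to
#'   `rsbm_loglik(G, g, spec)$log_likelihood`.
#' @export
rsbm_loglik_entropy <- function(G, g, spec, B = NULL) {
  ev <- rsbm_loglik(G, g, spec, B = B)
  if (!is.finite(ev$log_likelihood)) return(ev$log_likelihood)
  ev$kl_term - 2 * ev$cross_entropy_sum + 2 * sum(ev$prior$k * log(ev$prior$theta))
}

#' Maximum-likelihood block-pair rates
#'
#' Elementwise \eqn{\hat\omega_{rs} = m_{rs} / \Lambda_{rs}}, with
#' \eqn{\hat\omega_{rs} = 0} where both are zero.
#'
#' @param summary a [block_summary()].
#' @param Lambda the matching \eqn{\Lambda} matrix (e.g.
#'   `rsbm_loglik(...)$Lambda`).
#' @return A `B x B` matrix.
#' @export
mle_omega <- function(summary, Lambda) {
  m <- summary$m
  if (any(m > 0 & Lambda <= 0)) {
    stop("inconsistent parameters: m_rs > 0 where Lambda_rs = 0")
  }
  omega <- matrix(0, nrow(m), ncol(m))
  nz <- m > 0
  omega[nz] <- m[nz] / Lambda[nz]
  omega
}

#' Expected edge counts under the fitted model
#'
#' `lambda_matrix` returns the full matrix of expected edge counts
#' \eqn{\lambda_{ij} = \hat\omega_{g_i g_j} I_i I_j} for same-block pairs and
#' \eqn{\hat\omega_{g_i g_j} O_i O_j} otherwise, with \eqn{\hat\omega}
#' profiled at the given partition. `expected_edge_rate` extracts a single
#' pair. The diagonal holds \eqn{\lambda_{ii}} (self-loop rate
#' \eqn{\lambda_{ii}/2}).
#'
#' @inheritParams rsbm_loglik
#' @return `lambda_matrix`: an `n x n` symmetric matrix with node
#'   identifiers as dimnames.
#' @export
lambda_matrix <- function(G, g, spec, B = NULL) {
  ev <- rsbm_loglik(G, g, spec, B = B)
  rp <- ev$prior
  gv <- align_partition(g, G)
  om <- ev$omega_hat[gv, gv, drop = FALSE]
  same <- outer(gv, gv, "==")
  lam <- om * ifelse(same, outer(rp$I, rp$I), outer(rp$O, rp$O))
  dimnames(lam) <- list(G$nodes, G$nodes)
  lam
}

#' @rdname lambda_matrix
#' @param i,j node identifiers (or indices).
#' @return `expected_edge_rate`: a single number \eqn{\lambda_{ij}}.
#' @export
expected_edge_rate <- function(G, g, spec, i, j, B = NULL) {
  lam <- lambda_matrix(G, g, spec, B = B)
  if (is.character(i)) i <- match(i, G$nodes)
  if (is.character(j)) j <- match(j, G$nodes)
  lam[i, j]
}

#' Maximum-likelihood scale parameters theta
#'
#' At fixed prior in-degree ratios `f` and partition `g`, maximizes the
#' profile log-likelihood over the per-node scales \eqn{\theta_i} by damped
#' fixed-point iteration on the stationarity condition
#' \deqn{\theta_i = k_i \Big/ \left( \frac{m_{rr} f_i}{\sum_{l \in r} f_l
#'   \theta_l} + \frac{(\kappa_r - m_{rr})(1 - f_i)}{\sum_{l \in r}
#'   (1 - f_l)\theta_l} \right), \quad r = g_i,}
#' initialized at \eqn{\theta_i = k_i}. At the optimum the model preserves
#' the degree sequence: \eqn{\sum_j \lambda_{ij} = k_i} for every node. With
#' `f = 1/2` the fixed point is \eqn{\theta_i = k_i} exactly, the
#' degree-corrected model's degree preservation.
#'
#' @param G a [multigraph()].
#' @param g a partition.
#' @param f per-node prior in-degree ratios (scalar recycled, or named
#'   vector), in (0, 1].
#' @param tol relative tolerance on the degree residuals
#'   \eqn{|\sum_j \lambda_{ij} - k_i| / k_i} (default `1e-8`).
#' @param max_iter iteration cap (default `10000`).
#' @param damping step fraction toward the fixed-point update in (0, 1].
#' @return Named numeric vector of \eqn{\hat\theta_i} with attributes
#'   `iterations`, `converged` and `residual`. Warns on non-convergence and
#'   returns the best iterate.
#' @export
fit_theta_mle <- function(G, g, f, tol = 1e-8, max_iter = 10000, damping = 0.5) {
  stopifnot(inherits(G, "multigraph"))
  k <- as.numeric(G$deg)
  if (any(k == 0)) stop("isolated nodes not allowed")
  if (!is.null(names(f))) f <- as.numeric(f[G$nodes])
  f <- rep_len(as.numeric(f), G$n)
  if (any(f <= 0) || any(f > 1)) stop("f must lie in (0, 1]")
  bs <- block_summary(G, g)
  gv <- align_partition(g, G)
  m_in <- diag(bs$m)[gv]          # m_rr of the node's own block
  m_out <- (bs$kappa - diag(bs$m))[gv]

  theta <- k
  res <- Inf
  it <- 0L
  B <- bs$B
  while (it < max_iter) {
    it <- it + 1L
    SI <- numeric(B); SO <- numeric(B)
    aggI <- rowsum(f * theta, gv); SI[as.integer(rownames(aggI))] <- aggI[, 1L]
    aggO <- rowsum((1 - f) * theta, gv); SO[as.integer(rownames(aggO))] <- aggO[, 1L]
    den <- ifelse(m_in > 0, m_in * f / SI[gv], 0) +
           ifelse(m_out > 0, m_out * (1 - f) / SO[gv], 0)
    if (any(den <= 0)) {
      stop("degenerate configuration: a node with positive degree has no ",
           "reachable edge mass under the given f")
    }
    res <- max(abs(theta * den - k) / k)
    if (res <= tol) break
    theta <- theta + damping * (k / den - theta)
  }
  converged <- res <= tol
  if (!converged) {
    warning(sprintf("fit_theta_mle did not converge in %d iterations (residual %.3g)",
                    max_iter, res))
  }
  structure(stats::setNames(theta, G$nodes),
            iterations = it, converged = converged, residual = res)
}
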
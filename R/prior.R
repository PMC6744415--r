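#' Prior in-degree-ratio specifications
#'
#' A prior specification fixes, for every node `i`, the prior in-degree
#' ratio `f_i` (the target fraction of the node's edge endpoints that stay
#' inside its own block) and the scale `theta_i`, from which the model's
#' per-node rate parameters are `I_i = f_i * theta_i` (inside) and
#' `O_i = (1 - f_i) * theta_i` (outside). The available forms are:
#'
#' * `"rsbm_floor"`: `f_i = max(f, 1/k_i)` for a constant floor
#'   `f` in (0, 1) — the form used for the prior sweeps.
#' * `"rsbm_affine"`: `f_i = alpha + (1 - alpha)/k_i`, `alpha` in `[0, 1]`,
#'   a strictly decreasing function of degree with `f(1) = 1`.
#' * `"rsbm_pernode"`: explicit per-node table of `f_i`.
#' * `"degree_corrected"`: `I_i = O_i = k_i` (so `f_i = 1/2`,
#'   `theta_i = 2 k_i`); the degree-corrected stochastic block model, whose
#'   inference decisions coincide with any `f_i = 1/2` member of the family.
#' * `"standard"`: `I_i = O_i = 1` (so `f_i = 1/2`, `theta_i = 2`); the
#'   standard stochastic block model.
#'
#' Both parametric forms give `f(1) = 1`: a degree-one node must attach to
#' the block it belongs to.
#'
#' @param form one of the forms above.
#' @param f floor value for `"rsbm_floor"`, in (0, 1).
#' @param alpha mixing value for `"rsbm_affine"`, in `[0, 1]`.
#' @param f_pernode named numeric vector of per-node `f_i` in (0, 1] for
#'   `"rsbm_pernode"`.
#' @param theta `"degree"` (`theta_i = k_i`, the default operating point) or
#'   `"explicit"` (supply `theta_pernode`).
#' @param theta_pernode named numeric vector of per-node `theta_i > 0`.
#' @return An object of class `"prior_spec"`.
#' @seealso [resolve_prior()]
#' @export
prior_spec <- function(form = c("rsbm_floor", "rsbm_affine", "rsbm_pernode",
                                "degree_corrected", "standard"),
                       f = 0.8, alpha = NULL, f_pernode = NULL,
                       theta = c("degree", "explicit"), theta_pernode = NULL) {
  form <- match.arg(form)
  theta <- match.arg(theta)
  if (form == "rsbm_floor") {
    if (!is.numeric(f) || length(f) != 1L || f <= 0 || f >= 1) {
      stop("'f' must be a single value in (0, 1)")
    }
  }
  if (form == "rsbm_affine") {
    if (is.null(alpha)) stop("'alpha' is required for form 'rsbm_affine'")
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
      stop("'alpha' must be a single value in [0, 1]")
    }
  }
  if (form == "rsbm_pernode") {
    if (is.null(f_pernode) || is.null(names(f_pernode))) {
      stop("'f_pernode' must be a named vector for form 'rsbm_pernode'")
    }
    if (any(f_pernode <= 0) || any(f_pernode > 1)) {
      stop("per-node f values must lie in (0, 1]")
    }
  }
  if (theta == "explicit") {
    if (is.null(theta_pernode) || is.null(names(theta_pernode))) {
      stop("'theta_pernode' must be a named vector when theta = 'explicit'")
    }
    if (any(theta_pernode <= 0)) stop("per-node theta values must be positive")
  }
  structure(list(form = form, f = f, alpha = alpha, f_pernode = f_pernode,
                 theta = theta, theta_pernode = theta_pernode),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  desc <- switch(x$form,
    rsbm_floor = sprintf("RSBM, f_i = max(%g, 1/k_i)", x$f),
    rsbm_affine = sprintf("RSBM, f_i = %g + %g/k_i", x$alpha, 1 - x$alpha),
    rsbm_pernode = "RSBM, per-node f_i",
    degree_corrected = "degree-corrected SBM (I_i = O_i = k_i)",
    standard = "standard SBM (I_i = O_i = 1)")
  th <- if (x$form %in% c("degree_corrected", "standard")) ""
        else if (x$theta == "degree") ", theta_i = k_i" else ", explicit theta_i"
  cat("Prior spec: ", desc, th, "\n", sep = "")
  invisible(x)
}

#' Resolve a prior specification against a graph
#'
#' Evaluates the per-node prior quantities `(f_i, theta_i, I_i, O_i)` on the
#' degree sequence of `G`. Isolated nodes are rejected: the model requires
#' `k_i >= 1`.
#'
#' @param spec a [prior_spec()], or an already-resolved prior (returned
#'   unchanged).
#' @param G a [multigraph()].
#' @return A data frame of class `"resolved_prior"` with columns `node`,
#'   `k`, `f`, `theta`, `I`, `O`.
#' @export
resolve_prior <- function(spec, G) {
  if (inherits(spec, "resolved_prior")) return(spec)
  stopifnot(inherits(spec, "prior_spec"), inherits(G, "multigraph"))
  k <- as.numeric(G$deg)
  if (any(k == 0)) {
    stop("isolated node(s) not allowed: ",
         paste(utils::head(G$nodes[k == 0], 5L), collapse = ", "))
  }
  f <- switch(spec$form,
    standard = rep(0.5, G$n),
    degree_corrected = rep(0.5, G$n),
    rsbm_affine = spec$alpha + (1 - spec$alpha) / k,
    rsbm_floor = pmax(spec$f, 1 / k),
    rsbm_pernode = {
      fv <- spec$f_pernode[G$nodes]
      if (anyNA(fv)) {
        stop("f_pernode missing nodes: ",
             paste(utils::head(G$nodes[is.na(fv)], 5L), collapse = ", "))
      }
      as.numeric(fv)
    })
  theta <- if (spec$form == "standard") {
    rep(2, G$n)
  } else if (spec$form == "degree_corrected") {
    2 * k  # I_i = O_i = k_i, the canonical DCSBM factors (Lambda = kappa kappa)
  } else if (spec$theta == "degree") {
    k
  } else {
    tv <- spec$theta_pernode[G$nodes]
    if (anyNA(tv)) {
      stop("theta_pernode missing nodes: ",
           paste(utils::head(G$nodes[is.na(tv)], 5L), collapse = ", "))
    }
    as.numeric(tv)
  }
  out <- data.frame(node = G$nodes, k = k, f = f, theta = theta,
                    I = f * theta, O = (1 - f) * theta,
                    stringsAsFactors = FALSE)
  class(out) <- c("resolved_prior", "data.frame")
  out
}
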
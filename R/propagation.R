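#' Column-stochastic transition matrix of a module network
#'
#' Builds the unweighted symmetric adjacency matrix of the module network's
#' cross-talk edges and normalizes each column to sum to one. Columns of
#' isolated modules (no cross-talk partner) would be all-zero; they are
#' replaced by the uniform column 1/m, the standard PageRank repair for
#' dangling nodes, so the matrix is always column-stochastic.
#'
#' @param net a \code{module_network} from \code{\link{build_module_network}}.
#' @return an m x m numeric matrix with module names as dimnames, every
#'   column summing to 1.
#' @export
transition_matrix <- function(net) {
  stopifnot(inherits(net, "module_network"))
  m <- length(net$modules)
  if (m < 1) stop("module network has no modules")
  A <- matrix(0, m, m, dimnames = list(net$modules, net$modules))
  if (nrow(net$edges)) {
    ia <- match(net$edges$module_a, net$modules)
    ib <- match(net$edges$module_b, net$modules)
    A[cbind(ia, ib)] <- 1
    A[cbind(ib, ia)] <- 1
  }
  cs <- colSums(A)
  W <- A
  nz <- cs > 0
  W[, nz] <- sweep(A[, nz, drop = FALSE], 2, cs[nz], "/")
  W[, !nz] <- 1 / m
  W
}

#' Damped network propagation of module scores
#'
#' Iterates the PageRank-style update
#' \deqn{P_k = \lambda W P_{k-1} + (1 - \lambda) P_0}
#' until the L1 change drops below \code{tol}. \code{P0} (the prior: raw
#' disease module importance) is L1-normalized internally, so with a
#' column-stochastic W the total mass is conserved at every iteration and
#' the tolerance is scale-free. The fixed point solves the linear system
#' \code{(I - lambda W) P = (1 - lambda) P0}. Module rankings are invariant
#' to the normalization.
#'
#' @param W column-stochastic matrix from \code{\link{transition_matrix}}.
#' @param P0 named nonnegative numeric vector over the same modules, not
#'   all zero.
#' @param lambda damping factor in (0, 1): fraction of mass propagated
#'   through the network each step, 1 - lambda restarting from the prior.
#'   Default 0.85, the typical PageRank value.
#' @param tol L1 convergence threshold (default 1e-9).
#' @param max_iter iteration cap (default 1000).
#' @return object of class \code{propagation_result}: list with \code{P}
#'   (converged named vector), \code{P0} (normalized prior), \code{lambda},
#'   \code{iterations} and \code{residual} (final L1 change).
#' @export
propagate <- function(W, P0, lambda = 0.85, tol = 1e-9, max_iter = 1000) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (lambda <= 0 || lambda >= 1) stop("lambda must be in (0, 1)")
  mods <- colnames(W)
  .stop_if_not_named_numeric(P0, "P0")
  if (!all(mods %in% names(P0)))
    stop("P0 must cover every module of W")
  p0 <- P0[mods]
  if (any(p0 < 0)) stop("P0 must be nonnegative")
  s <- sum(p0)
  if (s == 0)
    stop("P0 is all zero: no prior information to propagate")
  p0 <- p0 / s
  p <- p0
  iter <- 0L
  residual <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    p_new <- lambda * drop(W %*% p) + (1 - lambda) * p0
    residual <- sum(abs(p_new - p))
    p <- p_new
    if (residual < tol) break
  }
  names(p) <- mods
  structure(list(P = p, P0 = p0, lambda = lambda, iterations = iter,
                 residual = residual),
            class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  cat("Network propagation over", length(x$P), "modules: lambda =",
      x$lambda, "| converged in", x$iterations,
      "iterations (L1 residual", format(x$residual, digits = 3), ")\n")
  invisible(x)
}

#' Rank modules by score
#'
#' Sorts modules by descending score, breaking ties lexicographically by
#' module name, and returns the top \code{top_n} (all if fewer exist).
#'
#' @param x a \code{propagation_result} or a named numeric score vector.
#' @param top_n number of modules to return (default 15; in the original
#'   application roughly 10\% of the module network).
#' @return data frame with columns \code{module} and \code{score}, ordered.
#' @export
rank_modules <- function(x, top_n = 15) {
  if (inherits(x, "propagation_result")) x <- x$P
  .stop_if_not_named_numeric(x, "scores")
  if (top_n < 1) stop("top_n must be >= 1")
  o <- order(-x, names(x))
  k <- min(top_n, length(x))
  data.frame(module = names(x)[o][seq_len(k)],
             score = unname(x[o])[seq_len(k)],
             stringsAsFactors = FALSE)
}
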
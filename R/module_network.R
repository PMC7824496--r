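# internal: integer edge matrix + node count, computed once per graph
.edge_index <- function(graph) {
  list(edges = igraph::ends(graph, igraph::E(graph), names = FALSE),
       n = igraph::vcount(graph),
       nodes = igraph::V(graph)$name)
}

# count edges with one endpoint in idxA and the other in idxB (logical masks)
.count_between <- function(edges, inA, inB) {
  e1 <- edges[, 1L]
  e2 <- edges[, 2L]
  sum((inA[e1] & inB[e2]) | (inB[e1] & inA[e2]))
}

#' Count PPI edges between two gene sets
#'
#' Counts graph edges \{u, v\} with u in A and v in B (in either order).
#' Each edge is counted once, so edges internal to the intersection of A
#' and B are not double-counted; with \code{A == B} the result is the
#' number of edges internal to A.
#'
#' @param graph undirected igraph with vertex names.
#' @param A,B nonempty character vectors of gene ids; members not present
#'   in the graph are ignored.
#' @return nonnegative integer count.
#' @export
inter_edge_count <- function(graph, A, B) {
  if (!length(A) || !length(B)) stop("A and B must be nonempty")
  ei <- .edge_index(graph)
  inA <- ei$nodes %in% A
  inB <- ei$nodes %in% B
  .count_between(ei$edges, inA, inB)
}

# shared permutation engine so build_module_network can reuse the edge index
.crosstalk <- function(ei, idxA, idxB, n_perm, seed, plus_one) {
  nA <- length(idxA)
  nB <- length(idxB)
  if (nA + nB > ei$n)
    stop("|A| + |B| exceeds the number of graph nodes")
  inA <- rep(FALSE, ei$n); inA[idxA] <- TRUE
  inB <- rep(FALSE, ei$n); inB[idxB] <- TRUE
  observed <- .count_between(ei$edges, inA, inB)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(ei$n, nA + nB)
      ra <- rep(FALSE, ei$n); ra[idx[seq_len(nA)]] <- TRUE
      rb <- rep(FALSE, ei$n); rb[idx[nA + seq_len(nB)]] <- TRUE
      .count_between(ei$edges, ra, rb)
    }, numeric(1))
  })
  p <- if (plus_one) (1 + sum(null_counts >= observed)) / (1 + n_perm)
       else mean(null_counts >= observed)
  list(p_value = p, observed = observed, null_counts = null_counts)
}

#' Permutation test for cross-talk between two modules
#'
#' Tests whether the number of PPI edges between gene sets A and B is
#' significantly high, against a null distribution obtained by drawing
#' \code{n_perm} pairs of disjoint uniform random node sets of sizes |A| and
#' |B| from the graph's node universe and counting the edges between them.
#' The one-sided p-value uses the permutation pseudo-count convention
#' p = (1 + #\{null >= observed\}) / (1 + n_perm), so it is never zero;
#' set \code{plus_one = FALSE} for the bare ratio.
#'
#' @inheritParams inter_edge_count
#' @param n_perm number of random draws (default 1000).
#' @param seed integer seed for reproducible draws, or NULL.
#' @param plus_one logical; use the pseudo-count p-value (default TRUE).
#' @return list with \code{p_value}, \code{observed} (inter-edge count) and
#'   \code{null_counts} (numeric vector of length \code{n_perm}).
#' @export
crosstalk_pvalue <- function(graph, A, B, n_perm = 1000, seed = NULL,
                             plus_one = TRUE) {
  if (!length(A) || !length(B)) stop("A and B must be nonempty")
  if (n_perm < 1) stop("n_perm must be >= 1")
  ei <- .edge_index(graph)
  iA <- which(ei$nodes %in% A)
  iB <- which(ei$nodes %in% B)
  # canonical argument order, so p(A, B) == p(B, A) under the same seed
  ka <- paste(length(iA), paste(iA, collapse = ","))
  kb <- paste(length(iB), paste(iB, collapse = ","))
  if (ka > kb) { tmp <- iA; iA <- iB; iB <- tmp }
  .crosstalk(ei, iA, iB, n_perm, seed, plus_one)
}

#' Build the module network
#'
#' Applies \code{\link{crosstalk_pvalue}} to every unordered pair of
#' modules, using a deterministic per-pair seed derived from \code{seed} and
#' the (sorted) module names, so results are independent of pair order.
#' Pairs with p below \code{alpha} become edges; all modules appear as
#' nodes, including those with no significant partner.
#'
#' @param graph undirected igraph with vertex names (the sampling universe
#'   for the permutation null is all graph nodes).
#' @param modules named list of gene sets, at least 2 modules.
#' @param alpha significance threshold on the per-pair p-value
#'   (default 0.01).
#' @param n_perm permutations per pair (default 1000).
#' @param seed master integer seed.
#' @param adjust \code{"none"} (default; the raw per-pair cutoff) or
#'   \code{"BH"} for a Benjamini-Hochberg adjustment across pairs before
#'   thresholding.
#' @return object of class \code{module_network}: list with \code{modules}
#'   (names), \code{pairs} (data frame: module_a, module_b, observed,
#'   p_value for every pair), \code{edges} (the significant subset),
#'   \code{alpha}, \code{n_perm}.
#' @export
build_module_network <- function(graph, modules, alpha = 0.01,
                                 n_perm = 1000, seed = 1L,
                                 adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(modules) < 2) stop("need at least 2 modules")
  if (is.null(names(modules)) || anyDuplicated(names(modules)))
    stop("modules must have unique names")
  ei <- .edge_index(graph)
  idx <- lapply(modules, function(m) which(ei$nodes %in% m))
  nms <- names(modules)
  cmb <- utils::combn(length(nms), 2)
  res <- lapply(seq_len(ncol(cmb)), function(j) {
    a <- cmb[1, j]; b <- cmb[2, j]
    ct <- .crosstalk(ei, idx[[a]], idx[[b]], n_perm,
                     .pair_seed(seed, nms[a], nms[b]), plus_one = TRUE)
    data.frame(module_a = nms[a], module_b = nms[b],
               observed = ct$observed, p_value = ct$p_value,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, res)
  rownames(pairs) <- NULL
  p_eff <- if (adjust == "BH") stats::p.adjust(pairs$p_value, "BH")
           else pairs$p_value
  edges <- pairs[p_eff < alpha, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(modules = nms, pairs = pairs, edges = edges,
                 alpha = alpha, n_perm = n_perm),
            class = "module_network")
}

#' @export
print.module_network <- function(x, ...) {
  cat("Module network:", length(x$modules), "modules,",
      nrow(x$edges), "cross-talk edges (p <", x$alpha, "at",
      x$n_perm, "permutations)\n")
  invisible(x)
}
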
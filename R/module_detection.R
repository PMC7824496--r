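#' MCODE-style vertex weights
#'
#' For each vertex v, the subgraph induced by v and its neighbours is
#' examined; if k is the largest core number in that subgraph, the weight of
#' v is k times the edge density of the highest k-core (the subgraph induced
#' by vertices of core number >= k). Dense, mutually connected
#' neighbourhoods therefore score high; isolated vertices score 0.
#'
#' @param graph an undirected igraph with vertex names.
#' @return named numeric vector of nonnegative weights, one per vertex.
#' @examples
#' g <- igraph::make_full_graph(5)
#' igraph::V(g)$name <- letters[1:5]
#' vertex_weights(g)  # all 4: core number 4, density 1
#' @export
vertex_weights <- function(graph) {
  if (igraph::vcount(graph) == 0) stop("graph is empty")
  vs <- igraph::V(graph)$name
  nbr <- igraph::as_adj_list(graph)
  w <- numeric(length(vs))
  names(w) <- vs
  for (i in seq_along(vs)) {
    nb <- unique(c(i, as.integer(nbr[[i]])))
    if (length(nb) == 1) next  # isolated vertex
    sub <- igraph::induced_subgraph(graph, nb)
    core <- igraph::coreness(sub)
    k <- max(core)
    if (k == 0) next
    ksub <- igraph::induced_subgraph(sub, which(core >= k))
    n <- igraph::vcount(ksub)
    d <- if (n > 1) 2 * igraph::ecount(ksub) / (n * (n - 1)) else 0
    w[i] <- k * d
  }
  w
}

#' Detect dense modules by seeded growth
#'
#' Mines dense, vertex-disjoint clusters from an interaction graph in the
#' style of MCODE. Vertices are weighted by \code{\link{vertex_weights}} and
#' visited in decreasing weight order (ties broken lexicographically by
#' vertex id). Each unassigned vertex seeds a cluster that grows by
#' repeatedly admitting unassigned neighbours whose weight is at least
#' \code{(1 - node_score_cutoff)} times the seed weight. With
#' \code{haircut}, vertices outside the cluster's 2-core are then removed.
#' Clusters with fewer than \code{min_size} members are discarded (their
#' vertices stay consumed, as in MCODE's single-pass scan). Surviving
#' clusters are named M1, M2, ... in order of decreasing seed weight.
#'
#' @param graph undirected igraph with vertex names.
#' @param min_size minimum cluster size retained (default 5).
#' @param node_score_cutoff admission slack as a fraction of the seed
#'   weight, in \code{[0, 1)} (default 0.2, the published MCODE default).
#' @param haircut logical; trim the cluster to its 2-core (default TRUE).
#' @return named list of character vectors (sorted gene ids), one per
#'   module, in seed-weight order.
#' @export
detect_modules <- function(graph, min_size = 5, node_score_cutoff = 0.2,
                           haircut = TRUE) {
  if (!is.numeric(min_size) || length(min_size) != 1 || min_size < 1)
    stop("min_size must be a single integer >= 1")
  if (node_score_cutoff < 0 || node_score_cutoff >= 1)
    stop("node_score_cutoff must be in [0, 1)")
  w <- vertex_weights(graph)
  vs <- names(w)
  ord <- order(-w, vs)
  nbr <- igraph::as_adj_list(graph)
  assigned <- logical(length(vs))
  modules <- list()
  for (si in ord) {
    if (assigned[si]) next
    thr <- (1 - node_score_cutoff) * w[si]
    assigned[si] <- TRUE
    members <- si
    frontier <- si
    while (length(frontier)) {
      cand <- unique(unlist(lapply(frontier, function(v)
        as.integer(nbr[[v]])), use.names = FALSE))
      cand <- cand[!assigned[cand] & w[cand] >= thr]
      if (!length(cand)) break
      assigned[cand] <- TRUE
      members <- c(members, cand)
      frontier <- cand
    }
    if (haircut && length(members) > 1) {
      sub <- igraph::induced_subgraph(graph, members)
      core <- igraph::coreness(sub)
      members <- members[core >= 2]
    } else if (haircut) {
      members <- integer(0)
    }
    if (length(members) >= min_size)
      modules[[length(modules) + 1L]] <- sort(vs[members])
  }
  if (length(modules))
    names(modules) <- paste0("M", seq_along(modules))
  else
    modules <- structure(list(), names = character(0))
  modules
}
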
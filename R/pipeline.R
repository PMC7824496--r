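#' Screen drugs for diseases
#'
#' Runs the full drug-screening pipeline for a set of diseases against a
#' set of drugs, with one of five scoring methods:
#' \describe{
#'   \item{\code{"mnbdr"}}{the full module-network method: disease gene
#'     scores are mapped to module importance, refined by damped
#'     propagation over the module network, and drugs are ranked by the
#'     rank-alignment indicator S against the disease's top modules. Drug
#'     importance vectors are \emph{not} propagated.}
#'   \item{\code{"module"}}{the module baseline: identical, but disease
#'     modules are ranked by raw importance with no propagation.}
#'   \item{\code{"ks"}, \code{"zhang"}, \code{"xsum"}}{classic gene-level
#'     connectivity baselines on top-k up/down signatures derived from the
#'     disease score vector.}
#' }
#' Connectivity baselines conventionally reward signature \emph{reversal}
#' (negative connectivity); here all methods rank by descending score with
#' perturbation-overlap semantics, so that the benchmark treats every
#' method identically.
#'
#' @param disease_scores named list of disease gene score vectors (named
#'   numeric, signed log fold-changes).
#' @param drug_scores named list of drug gene score vectors (named
#'   numeric, signed z-scores).
#' @param modules named list of gene sets (required for \code{"mnbdr"} and
#'   \code{"module"}).
#' @param graph interaction graph (required for \code{"mnbdr"} when
#'   \code{network} is not supplied).
#' @param method scoring method, see Details.
#' @param network optional precomputed \code{module_network}; built from
#'   \code{graph} and \code{modules} when NULL.
#' @param lambda,tol,max_iter propagation parameters, see
#'   \code{\link{propagate}}.
#' @param top_n number of top disease modules entering S (default 15).
#' @param alpha,n_perm,seed module-network construction parameters, see
#'   \code{\link{build_module_network}}.
#' @param n_up,n_down signature sizes for the connectivity baselines.
#' @param extreme_k extreme-gene count for \code{"xsum"}.
#' @return named list (one element per disease) of data frames with
#'   columns \code{drug_id}, \code{score}, \code{rank}, sorted by
#'   descending score (ties lexicographic by drug id).
#' @export
screen_drugs <- function(disease_scores, drug_scores, modules = NULL,
                         graph = NULL,
                         method = c("mnbdr", "module", "ks", "zhang",
                                    "xsum"),
                         network = NULL, lambda = 0.85, top_n = 15,
                         alpha = 0.01, n_perm = 1000, seed = 1L,
                         n_up = 100, n_down = 100, extreme_k = 100,
                         tol = 1e-9, max_iter = 1000) {
  method <- match.arg(method)
  stopifnot(is.list(disease_scores), !is.null(names(disease_scores)),
            is.list(drug_scores), !is.null(names(drug_scores)))
  if (method %in% c("mnbdr", "module")) {
    if (is.null(modules) || !length(modules))
      stop("method '", method, "' requires a module set")
    drug_imps <- lapply(drug_scores, module_importance, modules = modules)
    if (method == "mnbdr") {
      if (is.null(network)) {
        if (is.null(graph))
          stop("method 'mnbdr' requires a graph or a precomputed network")
        network <- build_module_network(graph, modules, alpha = alpha,
                                        n_perm = n_perm, seed = seed)
      }
      W <- transition_matrix(network)
    }
    out <- lapply(disease_scores, function(ds) {
      p0 <- module_importance(ds, modules)
      ranked <- if (method == "mnbdr") {
        rank_modules(propagate(W, p0, lambda = lambda, tol = tol,
                               max_iter = max_iter), top_n)
      } else {
        rank_modules(p0, top_n)
      }
      rank_drugs(ranked$module, drug_imps)
    })
  } else {
    out <- lapply(disease_scores, function(ds) {
      sig <- make_signature(ds, n_up = n_up, n_down = n_down)
      s <- vapply(drug_scores, function(dv) {
        switch(method,
          ks = ks_connectivity(
            sig, names(dv)[order(-dv, names(dv))]),
          zhang = zhang_score(sig, dv),
          xsum = xsum_score(sig, dv, extreme_k = extreme_k))
      }, numeric(1))
      o <- order(-s, names(s))
      data.frame(drug_id = names(s)[o], score = unname(s)[o],
                 rank = seq_along(s), stringsAsFactors = FALSE)
    })
  }
  out
}
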
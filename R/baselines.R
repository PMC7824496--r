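#' Build an up/down signature from a gene score vector
#'
#' Takes the \code{n_up} genes with the highest and the \code{n_down} genes
#' with the lowest signed scores (ties broken lexicographically by gene id)
#' as the up- and down-regulated tag lists of a connectivity-map style
#' signature.
#'
#' @param scores named numeric vector of signed gene scores.
#' @param n_up,n_down tag list sizes (default 100 per side).
#' @return list of class \code{signature} with character vectors \code{up}
#'   and \code{down} (disjoint by construction).
#' @export
make_signature <- function(scores, n_up = 100, n_down = 100) {
  .stop_if_not_named_numeric(scores, "scores")
  if (n_up < 1 || n_down < 1) stop("tag list sizes must be >= 1")
  if (n_up + n_down > length(scores))
    stop("n_up + n_down exceeds the number of genes")
  o <- order(-scores, names(scores))
  structure(list(up = names(scores)[o][seq_len(n_up)],
                 down = rev(names(scores)[o])[seq_len(n_down)]),
            class = "signature")
}

# one-tag-list KS statistic of the CMap connectivity score
.ks_tag <- function(tags, ranked) {
  n <- length(ranked)
  t <- length(tags)
  v <- match(tags, ranked)
  if (anyNA(v))
    stop("signature genes missing from the ranked list: ",
         paste(tags[is.na(v)], collapse = ", "))
  v <- sort(v)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

#' CMap KS connectivity score
#'
#' For each tag list (up, down) the Kolmogorov-Smirnov-style statistic
#' \code{a = max_j(j/t - V(j)/n)}, \code{b = max_j(V(j)/n - (j-1)/t)} is
#' computed over the sorted positions V(j) of the tags in the drug's ranked
#' gene list; the tag statistic is \code{a} if \code{a > b}, else
#' \code{-b}. The connectivity score is \code{KS_up - KS_down}, in
#' \code{[-2, 2]}: positive when the drug pushes the up-tags towards the
#' top and the down-tags towards the bottom of its ranking.
#'
#' @param sig a \code{signature} (see \code{\link{make_signature}}).
#' @param drug_ranked_genes character vector: all genes ranked by the
#'   drug's perturbation, strongest induction first.
#' @return numeric score in \code{[-2, 2]}.
#' @export
ks_connectivity <- function(sig, drug_ranked_genes) {
  stopifnot(inherits(sig, "signature"))
  .ks_tag(sig$up, drug_ranked_genes) - .ks_tag(sig$down, drug_ranked_genes)
}

#' Zhang connectivity score
#'
#' Genes are ranked by the magnitude of the drug's perturbation (largest
#' |score| gets the largest rank) and given the sign of the perturbation.
#' The score is the sum of these signed ranks over the signature genes,
#' with down-tags counted negatively, normalized by the maximum attainable
#' sum (the top |up|+|down| rank magnitudes), so it lies in \code{[-1, 1]}
#' and equals 1 exactly when the signature genes are the drug's most
#' extreme genes with matching signs.
#'
#' @inheritParams ks_connectivity
#' @param drug_scores named numeric vector of the drug's signed gene
#'   scores; must cover all signature genes.
#' @return numeric score in \code{[-1, 1]}.
#' @export
zhang_score <- function(sig, drug_scores) {
  stopifnot(inherits(sig, "signature"))
  .stop_if_not_named_numeric(drug_scores, "drug_scores")
  tags <- c(sig$up, sig$down)
  missing <- setdiff(tags, names(drug_scores))
  if (length(missing))
    stop("signature genes missing from the drug profile: ",
         paste(missing, collapse = ", "))
  r <- rank(abs(drug_scores), ties.method = "average")
  signed <- sign(drug_scores) * r
  num <- sum(signed[sig$up]) - sum(signed[sig$down])
  t <- length(tags)
  den <- sum(sort(r, decreasing = TRUE)[seq_len(t)])
  num / den
}

#' XSum connectivity score
#'
#' Zeroes every drug gene outside the \code{extreme_k} highest and
#' \code{extreme_k} lowest signed scores, then returns the sum of the
#' retained drug scores over the signature's up-tags minus the sum over its
#' down-tags.
#'
#' @inheritParams zhang_score
#' @param extreme_k number of genes retained at each extreme (default 100).
#' @return numeric score (unbounded; 0 when the signature misses the
#'   extremes entirely).
#' @export
xsum_score <- function(sig, drug_scores, extreme_k = 100) {
  stopifnot(inherits(sig, "signature"))
  .stop_if_not_named_numeric(drug_scores, "drug_scores")
  if (extreme_k < 1) stop("extreme_k must be >= 1")
  o <- order(-drug_scores, names(drug_scores))
  k <- min(extreme_k, length(drug_scores))
  keep <- union(names(drug_scores)[o][seq_len(k)],
                rev(names(drug_scores)[o])[seq_len(k)])
  x <- drug_scores
  x[setdiff(names(x), keep)] <- 0
  sum(x[intersect(sig$up, names(x))]) - sum(x[intersect(sig$down, names(x))])
}
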
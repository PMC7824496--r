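#' Rank-alignment drug--disease score S
#'
#' Scores one drug against one disease. The disease contributes its ordered
#' top-n modules (1st, 2nd, ..., nth by propagated importance); the drug
#' contributes an importance vector over \emph{all} modules, which is ranked
#' by descending Imp (ties broken lexicographically) to give each module a
#' position P in the drug's module list. The NDCG-inspired score is
#' \deqn{S = \sum_{i=1}^{n} \frac{V(i)}{|P(i) - i| + 1}}
#' where V(i) is the drug-side Imp of the disease's i-th module. A drug
#' whose strongly perturbed modules coincide positionally with the
#' disease's top modules gets denominators near 1 and a high S.
#'
#' @param disease_top ordered character vector of the disease's top module
#'   names (or the data frame returned by \code{\link{rank_modules}}).
#' @param drug_imp named nonnegative numeric vector of the drug's raw
#'   module importance over all modules; must cover every module in
#'   \code{disease_top}.
#' @return list with \code{S} (nonnegative score) and \code{n_used} (number
#'   of disease modules entering the sum).
#' @examples
#' # perfect positional agreement: denominators all 1
#' drug_disease_score(c("Ma", "Mb"), c(Ma = 4, Mb = 2))$S  # 6
#' @export
drug_disease_score <- function(disease_top, drug_imp) {
  if (is.data.frame(disease_top)) disease_top <- disease_top$module
  if (!length(disease_top)) stop("disease_top must be nonempty")
  .stop_if_not_named_numeric(drug_imp, "drug_imp")
  missing <- setdiff(disease_top, names(drug_imp))
  if (length(missing))
    stop("modules absent from the drug importance vector: ",
         paste(missing, collapse = ", "))
  ranked <- names(drug_imp)[order(-drug_imp, names(drug_imp))]
  pos <- match(disease_top, ranked)
  i <- seq_along(disease_top)
  v <- unname(drug_imp[disease_top])
  list(S = sum(v / (abs(pos - i) + 1)), n_used = length(i))
}

#' Rank all drugs against one disease
#'
#' Computes \code{\link{drug_disease_score}} for every drug and returns the
#' drugs sorted by descending S, ties broken lexicographically by drug id.
#'
#' @inheritParams drug_disease_score
#' @param drug_imps named list of drug importance vectors.
#' @return data frame with columns \code{drug_id}, \code{score} (S) and
#'   \code{rank}.
#' @export
rank_drugs <- function(disease_top, drug_imps) {
  if (!length(drug_imps)) stop("need at least one drug")
  if (is.null(names(drug_imps)) || anyDuplicated(names(drug_imps)))
    stop("drug_imps must have unique names")
  s <- vapply(drug_imps, function(imp)
    drug_disease_score(disease_top, imp)$S, numeric(1))
  o <- order(-s, names(s))
  data.frame(drug_id = names(s)[o], score = unname(s)[o],
             rank = seq_along(s), stringsAsFactors = FALSE)
}
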
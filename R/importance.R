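#' Gene-level log2 fold-changes from case/control expression matrices
#'
#' Averages expression within the case and control groups and returns the
#' per-gene log2 ratio \code{log2((mean_case + pseudocount) /
#' (mean_control + pseudocount))}. Inputs must be nonnegative
#' intensities or counts with genes as rows; a warning is raised when a
#' group has fewer than three samples, mirroring the usual inclusion rule
#' for stable disease signatures.
#'
#' @param case_matrix,control_matrix numeric matrices (genes x samples)
#'   with identical rownames (gene ids).
#' @param pseudocount positive offset stabilising the ratio for low
#'   expression (default 1).
#' @return named numeric vector of signed log2 fold-changes.
#' @export
fold_changes <- function(case_matrix, control_matrix, pseudocount = 1) {
  case_matrix <- as.matrix(case_matrix)
  control_matrix <- as.matrix(control_matrix)
  if (is.null(rownames(case_matrix)) || is.null(rownames(control_matrix)))
    stop("expression matrices must have gene rownames")
  if (!identical(sort(rownames(case_matrix)), sort(rownames(control_matrix))))
    stop("case and control matrices must share the same gene set")
  control_matrix <- control_matrix[rownames(case_matrix), , drop = FALSE]
  if (any(case_matrix < 0) || any(control_matrix < 0))
    stop("expression values must be nonnegative")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (ncol(case_matrix) < 3 || ncol(control_matrix) < 3)
    warning("fewer than 3 samples in a group; fold-changes may be unstable")
  f <- log2((rowMeans(case_matrix) + pseudocount) /
              (rowMeans(control_matrix) + pseudocount))
  names(f) <- rownames(case_matrix)
  f
}

#' Map gene scores into module space via the Imp statistic
#'
#' For each module, let Fmax and Fmin be the maximum and minimum score over
#' the module's genes present in \code{scores}. The module importance is
#' \deqn{Imp = Fmax - Fmin \quad \mathrm{if}\ Fmax > 0\ \mathrm{and}\ Fmin < 0,}
#' \deqn{Imp = \max(|Fmax|, |Fmin|) \quad \mathrm{otherwise,}}
#' i.e. the score range when the module's perturbations straddle zero and
#' the largest absolute perturbation otherwise. Genes absent from
#' \code{scores} are ignored; a module with no measured gene scores 0, so
#' the importance vector always covers every module. The same transform
#' applies to disease fold-change vectors and drug z-score vectors.
#'
#' @param scores named numeric vector of signed gene scores.
#' @param modules named list of gene sets.
#' @return named nonnegative numeric vector, one entry per module.
#' @examples
#' module_importance(c(a = 2, b = -1, c = 0.5),
#'                   list(M1 = c("a", "b", "c")))  # 3: range straddles 0
#' @export
module_importance <- function(scores, modules) {
  .stop_if_not_named_numeric(scores, "scores")
  if (!length(modules)) stop("need at least one module")
  vapply(modules, function(genes) {
    v <- scores[genes[genes %in% names(scores)]]
    if (!length(v)) return(0)
    fmax <- max(v)
    fmin <- min(v)
    if (fmax > 0 && fmin < 0) fmax - fmin else max(abs(fmax), abs(fmin))
  }, numeric(1))
}
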
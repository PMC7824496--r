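#' ROC area under the curve
#'
#' Computes the AUC as the Mann-Whitney probability that a random positive
#' outscores a random negative, with ties counted one half.
#'
#' @param scores numeric vector of ranking scores (higher = more likely
#'   positive).
#' @param labels logical vector of the same length; must contain at least
#'   one TRUE and one FALSE.
#' @return AUC in \code{[0, 1]}.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("need at least one positive and one negative label")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ROC points with tie grouping: (FPR, TPR) from (0,0) to (1,1)
.roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  last_of_group <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(!y)[last_of_group]
  list(fpr = c(0, fp / sum(!labels)), tpr = c(0, tp / sum(labels)))
}

#' Partial AUC at low false-positive rate (AUC0.1)
#'
#' Trapezoidal area under the ROC curve restricted to
#' \code{FPR <= fpr_max}, with linear interpolation at the boundary. The
#' value is \emph{unnormalized}: the maximum is \code{fpr_max} (perfect
#' early retrieval) and the chance level is \code{fpr_max^2 / 2} (0.005 at
#' the default 0.1). This early-retrieval index is the main criterion in
#' drug repositioning, where only the top of a ranked list is actionable.
#'
#' @inheritParams roc_auc
#' @param fpr_max upper FPR bound of the integration strip (default 0.1).
#' @return partial area in \code{[0, fpr_max]}.
#' @export
auc01 <- function(scores, labels, fpr_max = 0.1) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (sum(labels) == 0 || sum(!labels) == 0)
    stop("need at least one positive and one negative label")
  if (fpr_max <= 0 || fpr_max > 1) stop("fpr_max must be in (0, 1]")
  pts <- .roc_points(scores, labels)
  area <- 0
  for (i in seq_len(length(pts$fpr) - 1)) {
    x0 <- pts$fpr[i]; x1 <- pts$fpr[i + 1]
    y0 <- pts$tpr[i]; y1 <- pts$tpr[i + 1]
    if (x0 >= fpr_max) break
    if (x1 > fpr_max) {
      y1 <- if (x1 > x0) y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0) else y1
      x1 <- fpr_max
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area
}

#' Evaluate ranked drug lists against a benchmark standard
#'
#' For each disease, positives are the benchmark pairs for that disease and
#' negatives are all other candidate drugs in its ranking; per-disease AUC
#' and (unnormalized) AUC0.1 are computed and averaged without weighting.
#' Diseases whose candidates contain no positive, or only positives, are
#' excluded with a warning.
#'
#' @param rankings named list, one entry per disease: a data frame with
#'   columns \code{drug_id} and \code{score} (as produced by
#'   \code{\link{screen_drugs}}).
#' @param standard a \code{benchmark_standard}.
#' @param fpr_max FPR bound for the partial AUC (default 0.1).
#' @return object of class \code{evaluation_report}: list with
#'   \code{per_disease} (data frame: disease_id, auc, auc01, n_pos,
#'   n_neg), \code{AvgAUC} and \code{AvgAUC0.1}.
#' @export
evaluate <- function(rankings, standard, fpr_max = 0.1) {
  stopifnot(inherits(standard, "benchmark_standard"))
  if (!length(rankings) || is.null(names(rankings)))
    stop("rankings must be a named list (one entry per disease)")
  rows <- list()
  for (d in names(rankings)) {
    r <- rankings[[d]]
    pos_drugs <- standard$pairs$drug_id[standard$pairs$disease_id == d]
    labels <- r$drug_id %in% pos_drugs
    if (!any(labels) || all(labels)) {
      warning("disease ", d, " has ",
              if (any(labels)) "no negatives" else "no positives",
              " among its candidates; excluded from evaluation")
      next
    }
    rows[[d]] <- data.frame(
      disease_id = d,
      auc = roc_auc(r$score, labels),
      auc01 = auc01(r$score, labels, fpr_max),
      n_pos = sum(labels), n_neg = sum(!labels),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no evaluable disease (every disease was excluded)")
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  structure(list(per_disease = per,
                 AvgAUC = mean(per$auc),
                 AvgAUC0.1 = mean(per$auc01),
                 fpr_max = fpr_max),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation over", nrow(x$per_disease), "diseases\n")
  cat(sprintf("  AvgAUC    = %.4f\n", x$AvgAUC))
  cat(sprintf("  AvgAUC%g = %.4f (chance %.4g, max %g)\n",
              x$fpr_max, x$AvgAUC0.1, x$fpr_max^2 / 2, x$fpr_max))
  invisible(x)
}

#' Permutation p-value for an average ranking metric
#'
#' Tests whether the observed average metric (AvgAUC or AvgAUC0.1) exceeds
#' what random drug--disease assignments produce. Each permutation
#' reassigns every disease's positives uniformly at random among that
#' disease's candidate drugs, preserving per-disease positive counts, and
#' recomputes the average metric. Two tail probabilities are reported: the
#' empirical pseudo-count p-value
#' \code{(1 + #\{null >= observed\}) / (1 + n_perm)}, which can never fall
#' below \code{1/(1 + n_perm)}, and a Gaussian approximation from the null
#' sample's mean and standard deviation, which can resolve far smaller
#' tails than the draw count allows.
#'
#' @inheritParams evaluate
#' @param metric \code{"AvgAUC"} (default) or \code{"AvgAUC0.1"}.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed, or NULL.
#' @return object of class \code{permutation_test}: list with
#'   \code{observed}, \code{p_empirical}, \code{p_gaussian},
#'   \code{null_mean}, \code{null_sd}, \code{n_perm}, \code{metric}.
#' @export
permutation_pvalue <- function(rankings, standard,
                               metric = c("AvgAUC", "AvgAUC0.1"),
                               n_perm = 10000, seed = NULL,
                               fpr_max = 0.1) {
  metric <- match.arg(metric)
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs_report <- evaluate(rankings, standard, fpr_max)
  observed <- if (metric == "AvgAUC") obs_report$AvgAUC
              else obs_report$AvgAUC0.1
  kept <- obs_report$per_disease$disease_id
  # fixed per-disease material: scores (and ranks for the AUC fast path)
  mat <- lapply(kept, function(d) {
    r <- rankings[[d]]
    n_pos <- obs_report$per_disease$n_pos[
      obs_report$per_disease$disease_id == d]
    list(scores = r$score, ranks = rank(r$score, ties.method = "average"),
         n = length(r$score), n_pos = n_pos)
  })
  null_stat <- function() {
    mean(vapply(mat, function(m) {
      idx <- sample.int(m$n, m$n_pos)
      if (metric == "AvgAUC") {
        (sum(m$ranks[idx]) - m$n_pos * (m$n_pos + 1) / 2) /
          (m$n_pos * (m$n - m$n_pos))
      } else {
        lab <- logical(m$n)
        lab[idx] <- TRUE
        auc01(m$scores, lab, fpr_max)
      }
    }, numeric(1)))
  }
  null <- with_seed(seed,
    vapply(seq_len(n_perm), function(i) null_stat(), numeric(1)))
  mu <- mean(null)
  sdev <- stats::sd(null)
  structure(list(
    observed = observed,
    p_empirical = (1 + sum(null >= observed)) / (1 + n_perm),
    p_gaussian = if (is.na(sdev) || sdev == 0) NA_real_
                 else stats::pnorm(observed, mu, sdev, lower.tail = FALSE),
    null_mean = mu, null_sd = sdev,
    n_perm = n_perm, metric = metric),
    class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test on %s: observed %.4f vs null %.4f (sd %.4f)\n",
              x$metric, x$observed, x$null_mean, x$null_sd))
  cat(sprintf("  empirical p = %.4g (floor 1/%d), Gaussian p = %.4g\n",
              x$p_empirical, x$n_perm + 1, x$p_gaussian))
  invisible(x)
}
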
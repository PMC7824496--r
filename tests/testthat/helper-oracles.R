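# fixtures built in code and independent brute-force oracles;
# oracles deliberately use naive loops, not the package's code paths

graph_from_edges <- function(from, to, confidence = 990) {
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to,
               confidence = rep_len(confidence, length(from))),
    directed = FALSE)
}

# a clique on the given vertex names
clique_edges <- function(vs) {
  cmb <- utils::combn(vs, 2)
  data.frame(from = cmb[1, ], to = cmb[2, ], stringsAsFactors = FALSE)
}

# O(|A||B|) double-loop inter-set edge count on an edge data frame
bf_inter_count <- function(edf, A, B) {
  cnt <- 0L
  for (i in seq_len(nrow(edf))) {
    u <- edf$from[i]; v <- edf$to[i]
    if (u == v) next
    if ((u %in% A && v %in% B) || (u %in% B && v %in% A)) cnt <- cnt + 1L
  }
  cnt
}

# scalar two-branch importance oracle
bf_imp <- function(values) {
  if (!length(values)) return(0)
  fmax <- max(values); fmin <- min(values)
  if (fmax > 0 && fmin < 0) fmax - fmin else max(abs(fmax), abs(fmin))
}

# pairwise Mann-Whitney AUC oracle (ties count 1/2)
bf_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# explicit-loop KS tag statistic
bf_ks_tag <- function(tags, ranked) {
  n <- length(ranked); t <- length(tags)
  v <- sort(match(tags, ranked))
  a <- -Inf; b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - v[j] / n)
    b <- max(b, v[j] / n - (j - 1) / t)
  }
  if (a > b) a else -b
}

bf_ks <- function(up, down, ranked)
  bf_ks_tag(up, ranked) - bf_ks_tag(down, ranked)

# direct Zhang recomputation
bf_zhang <- function(up, down, drug) {
  r <- rank(abs(drug), ties.method = "average")
  signed <- sign(drug) * r
  t <- length(up) + length(down)
  (sum(signed[up]) - sum(signed[down])) /
    sum(sort(r, decreasing = TRUE)[seq_len(t)])
}

# truncate-and-sum XSum recomputation
bf_xsum <- function(up, down, drug, k) {
  o <- order(-drug, names(drug))
  keep <- union(names(drug)[o][seq_len(min(k, length(drug)))],
                rev(names(drug)[o])[seq_len(min(k, length(drug)))])
  x <- ifelse(names(drug) %in% keep, drug, 0)
  names(x) <- names(drug)
  sum(x[up]) - sum(x[down])
}

# best Jaccard overlap of each planted set against any detected module
best_jaccard <- function(planted, detected) {
  vapply(planted, function(pm) {
    if (!length(detected)) return(0)
    max(vapply(detected, function(dm)
      length(intersect(pm, dm)) / length(union(pm, dm)), numeric(1)))
  }, numeric(1))
}
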
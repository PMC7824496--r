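#' Read a STRING-style PPI edge list, keeping high-confidence interactions
#'
#' Parses a whitespace- or tab-delimited edge list with at least three
#' columns (protein_a, protein_b, combined_score; STRING convention, scores
#' in 0--1000) and returns the undirected interaction graph restricted to
#' edges whose confidence is at least \code{min_confidence}. Self-loops are
#' dropped, duplicate unordered pairs are collapsed (keeping the highest
#' confidence seen), and nodes left without any surviving edge are removed.
#' A header line is auto-detected by a non-numeric third field.
#'
#' @param path path to the edge-list file.
#' @param min_confidence inclusive confidence threshold in \code{[0, 1000]};
#'   the default 770 restricts STRING to high-confidence interactions.
#' @return an undirected \pkg{igraph} graph with vertex names and an edge
#'   attribute \code{confidence}.
#' @seealso \code{\link{write_ppi}}
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tb\t800", "b\tc\t700"), f)
#' g <- read_ppi(f, min_confidence = 770)
#' igraph::ecount(g)  # 1
#' @export
read_ppi <- function(path, min_confidence = 770) {
  if (!is.numeric(min_confidence) || length(min_confidence) != 1 ||
      min_confidence < 0 || min_confidence > 1000)
    stop("min_confidence must be a single number in [0, 1000]")
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  if (length(fields) == 0) {
    warning("no interactions at or above confidence ", min_confidence,
            "; returning an empty graph")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  # header detection: non-numeric third field on the first line
  first <- fields[[1]]
  has_header <- length(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(first[3])))
  if (has_header) {
    fields <- fields[-1]
    lineno <- lineno[-1]
  }
  n_ok <- vapply(fields, length, integer(1)) >= 3
  if (any(!n_ok))
    stop("malformed line ", lineno[which(!n_ok)[1]],
         ": expected at least 3 fields (node, node, score)")
  a <- vapply(fields, `[`, character(1), 1)
  b <- vapply(fields, `[`, character(1), 2)
  score <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
  if (anyNA(score))
    stop("malformed line ", lineno[which(is.na(score))[1]],
         ": non-numeric confidence score")
  ok <- score >= min_confidence & a != b
  a <- a[ok]; b <- b[ok]; score <- score[ok]
  if (length(a) == 0) {
    warning("no interactions at or above confidence ", min_confidence,
            "; returning an empty graph")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  # collapse duplicate unordered pairs, keeping the maximum confidence
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  o <- order(key, -score)
  first_of_pair <- !duplicated(key[o])
  sel <- o[first_of_pair]
  g <- igraph::graph_from_data_frame(
    data.frame(from = pmin(a, b)[sel], to = pmax(a, b)[sel],
               confidence = score[sel], stringsAsFactors = FALSE),
    directed = FALSE)
  g
}

#' Write an interaction graph as a three-column edge list
#'
#' Inverse of \code{\link{read_ppi}}: writes one tab-separated line per edge
#' (protein_a, protein_b, combined_score) with a header.
#'
#' @param graph an undirected igraph with vertex names; a numeric edge
#'   attribute \code{confidence} is used if present, else 1000.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_ppi <- function(graph, path) {
  df <- igraph::as_data_frame(graph, what = "edges")
  conf <- if ("confidence" %in% names(df)) df$confidence
          else rep(1000, nrow(df))
  out <- data.frame(protein_a = df$from, protein_b = df$to,
                    combined_score = conf)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read and write module sets in GMT format
#'
#' A module set is a named list of character vectors (gene identifiers).
#' The GMT dialect used here is one line per module: name, description and
#' members, tab-separated; on write the description field repeats the module
#' name. \code{read_modules(write_modules(x, f))} recovers \code{x} up to
#' member order.
#'
#' @param modules named list of character vectors; names must be unique.
#' @param path file path.
#' @return \code{read_modules}: a named list of character vectors.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' write_modules(list(M1 = c("a", "b", "c", "d", "e")), f)
#' read_modules(f)
#' @export
write_modules <- function(modules, path) {
  if (length(modules) && anyDuplicated(names(modules)))
    stop("module names must be unique")
  lines <- vapply(seq_along(modules), function(i) {
    paste(c(names(modules)[i], names(modules)[i], modules[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_modules
#' @export
read_modules <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(structure(list(), names = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad))
    stop("malformed GMT line ", bad[1],
         ": expected name, description and at least one member")
  nms <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(nms))
    stop("duplicate module name in GMT file: ",
         nms[duplicated(nms)][1])
  mods <- lapply(fields, function(f) f[-(1:2)])
  names(mods) <- nms
  mods
}

#' Read a benchmark standard of known drug--disease pairs
#'
#' Reads a two-column TSV (drug_id, disease_id) of clinically supported
#' indications, deduplicates the pairs, and takes the drug universe to be
#' all drugs seen in the file.
#'
#' @param path path to a two-column tab-separated file, no header.
#' @return an object of class \code{benchmark_standard}: a list with
#'   \code{pairs} (data frame with columns \code{drug_id},
#'   \code{disease_id}) and \code{drug_universe} (character vector).
#' @export
read_benchmark <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(benchmark_standard(
      data.frame(drug_id = character(0), disease_id = character(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != 2)
  if (length(bad))
    stop("malformed benchmark line ", bad[1],
         ": expected exactly 2 tab-separated columns (drug_id, disease_id)")
  df <- data.frame(drug_id = vapply(fields, `[`, character(1), 1),
                   disease_id = vapply(fields, `[`, character(1), 2),
                   stringsAsFactors = FALSE)
  benchmark_standard(df)
}

#' Construct a benchmark standard from a pair table
#'
#' @param pairs data frame with columns \code{drug_id} and
#'   \code{disease_id}; duplicate rows are collapsed.
#' @param drug_universe drugs eligible for ranking; defaults to all drugs in
#'   \code{pairs}. Every drug in \code{pairs} must belong to it.
#' @return a \code{benchmark_standard} object.
#' @export
benchmark_standard <- function(pairs, drug_universe = NULL) {
  stopifnot(is.data.frame(pairs),
            all(c("drug_id", "disease_id") %in% names(pairs)))
  pairs <- unique(pairs[, c("drug_id", "disease_id")])
  rownames(pairs) <- NULL
  if (is.null(drug_universe)) drug_universe <- sort(unique(pairs$drug_id))
  if (!all(pairs$drug_id %in% drug_universe))
    stop("every benchmark pair's drug must be in the drug universe")
  structure(list(pairs = pairs, drug_universe = drug_universe),
            class = "benchmark_standard")
}

#' @export
print.benchmark_standard <- function(x, ...) {
  cat("Benchmark standard:", nrow(x$pairs), "drug-disease pairs,",
      length(unique(x$pairs$disease_id)), "diseases,",
      length(x$drug_universe), "drugs in universe\n")
  invisible(x)
}

#' Read and write gene score vectors
#'
#' A gene score vector is a named numeric vector of signed per-gene
#' perturbation values (log fold-changes for diseases, z-scores for drugs),
#' stored as a two-column TSV (gene_id, value) without a header.
#'
#' @param scores named numeric vector.
#' @param path file path.
#' @return \code{read_scores}: a named numeric vector.
#' @export
write_scores <- function(scores, path) {
  .stop_if_not_named_numeric(scores, "scores")
  utils::write.table(
    data.frame(gene_id = names(scores), value = unname(scores)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(structure(numeric(0), names = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != 2)
  if (length(bad))
    stop("malformed score line ", bad[1],
         ": expected gene_id<TAB>value")
  v <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  if (anyNA(v))
    stop("malformed score line ", which(is.na(v))[1], ": non-numeric value")
  names(v) <- vapply(fields, `[`, character(1), 1)
  v
}
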
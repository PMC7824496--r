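#' Simulate a PPI network with planted modules and cross-talks
#'
#' Generates a synthetic interaction graph emulating a confidence-filtered
#' PPI network: \code{n_modules} vertex-disjoint cliques of size
#' \code{module_size} (the planted modules), Bernoulli bipartite edges with
#' probability \code{crosstalk_edge_prob} between designated cross-talk
#' module pairs, and a sparse Erdos-Renyi background with edge probability
#' \code{background_edge_prob} over every gene pair that is not internal to
#' the planted module set. Restricting the background in this way keeps
#' inter-module connectivity under the sole control of the cross-talk
#' parameter, so the module-recovery and cross-talk ground truths are
#' unambiguous. Cross-talk pairs are assigned disjointly first
#' ((1,2), (3,4), ...) and, if more are requested than
#' \code{floor(n_modules/2)}, drawn at random from the remaining pairs.
#'
#' Everything is a pure function of \code{seed}.
#'
#' @param n_modules number of planted cliques (default 12).
#' @param module_size clique size, at least 5 so planted modules survive
#'   the retention rule of \code{\link{detect_modules}} (default 8).
#' @param n_crosstalk_pairs number of module pairs with planted cross-talk
#'   (default 6).
#' @param crosstalk_edge_prob Bernoulli probability of each bipartite edge
#'   within a cross-talk pair (default 0.25).
#' @param n_background_genes genes outside any planted module
#'   (default 600).
#' @param background_edge_prob Erdos-Renyi background edge probability
#'   (default 0.005).
#' @param seed integer seed.
#' @return list with \code{graph} (igraph; planted edges carry confidence
#'   990, background edges 770--999) and \code{truth} (class
#'   \code{synthetic_truth}): \code{modules} (named list of gene sets),
#'   \code{crosstalk_pairs} (2-column matrix of module names),
#'   \code{genes} (all gene ids) and \code{params}.
#' @export
simulate_ppi <- function(n_modules = 12, module_size = 8,
                         n_crosstalk_pairs = 6, crosstalk_edge_prob = 0.25,
                         n_background_genes = 600,
                         background_edge_prob = 0.005, seed = 1L) {
  if (module_size < 5)
    stop("module_size must be >= 5 (smaller clusters are not retained as modules)")
  if (n_modules < 1 || n_background_genes < 0)
    stop("infeasible sizes")
  max_pairs <- n_modules * (n_modules - 1) / 2
  if (n_crosstalk_pairs > max_pairs)
    stop("n_crosstalk_pairs exceeds the number of module pairs")
  if (crosstalk_edge_prob < 0 || crosstalk_edge_prob > 1 ||
      background_edge_prob < 0 || background_edge_prob > 1)
    stop("edge probabilities must be in [0, 1]")

  n_mod_genes <- n_modules * module_size
  genes <- sprintf("g%04d", seq_len(n_mod_genes + n_background_genes))
  mod_names <- sprintf("M%02d", seq_len(n_modules))
  modules <- lapply(seq_len(n_modules), function(i)
    genes[((i - 1) * module_size + 1):(i * module_size)])
  names(modules) <- mod_names
  bg_genes <- if (n_background_genes > 0)
    genes[(n_mod_genes + 1):length(genes)] else character(0)

  # cross-talk pairs: disjoint matching first, random extras after
  disjoint <- floor(n_modules / 2)
  base_pairs <- if (disjoint > 0)
    cbind(seq_len(disjoint) * 2 - 1, seq_len(disjoint) * 2)[
      seq_len(min(n_crosstalk_pairs, disjoint)), , drop = FALSE]
  else matrix(integer(0), 0, 2)

  with_seed(seed, {
    if (n_crosstalk_pairs > disjoint) {
      all_pairs <- t(utils::combn(n_modules, 2))
      key <- function(m) paste(m[, 1], m[, 2])
      pool <- all_pairs[!(key(all_pairs) %in% key(base_pairs)), ,
                        drop = FALSE]
      extra <- pool[sample.int(nrow(pool),
                               n_crosstalk_pairs - disjoint), ,
                    drop = FALSE]
      ct_pairs <- rbind(base_pairs, extra)
    } else ct_pairs <- base_pairs

    edges <- list()
    # planted cliques
    for (i in seq_len(n_modules)) {
      cmb <- utils::combn(modules[[i]], 2)
      edges[[length(edges) + 1L]] <-
        data.frame(from = cmb[1, ], to = cmb[2, ], confidence = 990,
                   stringsAsFactors = FALSE)
    }
    # cross-talk bipartite edges
    if (nrow(ct_pairs) > 0 && crosstalk_edge_prob > 0) {
      for (j in seq_len(nrow(ct_pairs))) {
        a <- modules[[ct_pairs[j, 1]]]
        b <- modules[[ct_pairs[j, 2]]]
        grid <- expand.grid(from = a, to = b, stringsAsFactors = FALSE)
        keep <- stats::runif(nrow(grid)) < crosstalk_edge_prob
        if (any(keep))
          edges[[length(edges) + 1L]] <-
            data.frame(grid[keep, , drop = FALSE], confidence = 990)
      }
    }
    # ER background: background-background and background-module pairs
    if (length(bg_genes) > 1 && background_edge_prob > 0) {
      cmb <- utils::combn(bg_genes, 2)
      keep <- stats::runif(ncol(cmb)) < background_edge_prob
      if (any(keep))
        edges[[length(edges) + 1L]] <- data.frame(
          from = cmb[1, keep], to = cmb[2, keep],
          confidence = sample(770:999, sum(keep), replace = TRUE),
          stringsAsFactors = FALSE)
    }
    if (length(bg_genes) > 0 && n_mod_genes > 0 &&
        background_edge_prob > 0) {
      grid <- expand.grid(from = bg_genes, to = genes[seq_len(n_mod_genes)],
                          stringsAsFactors = FALSE)
      keep <- stats::runif(nrow(grid)) < background_edge_prob
      if (any(keep))
        edges[[length(edges) + 1L]] <- data.frame(
          grid[keep, , drop = FALSE],
          confidence = sample(770:999, sum(keep), replace = TRUE))
    }
    edf <- do.call(rbind, edges)
    g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                       vertices = genes)
    truth <- structure(list(
      modules = modules,
      crosstalk_pairs = cbind(mod_names[ct_pairs[, 1]],
                              mod_names[ct_pairs[, 2]]),
      genes = genes,
      params = list(n_modules = n_modules, module_size = module_size,
                    n_crosstalk_pairs = n_crosstalk_pairs,
                    crosstalk_edge_prob = crosstalk_edge_prob,
                    n_background_genes = n_background_genes,
                    background_edge_prob = background_edge_prob,
                    seed = seed)),
      class = "synthetic_truth")
    list(graph = g, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth:", length(x$modules), "planted modules of size",
      x$params$module_size, "|", nrow(x$crosstalk_pairs),
      "cross-talk pairs |", length(x$genes), "genes\n")
  invisible(x)
}

#' Simulate a gene score vector with planted module signal
#'
#' Draws a signed perturbation score for every gene of the synthetic
#' universe: background genes from Normal(0, \code{noise_sd}), genes inside
#' the driver modules from \code{sign * effect_size +
#' Normal(0, noise_sd)} where the signs are a balanced random shuffle of
#' +/- over the module's genes, drawn independently per condition. The
#' within-module sign mixing guarantees that driver-module scores straddle
#' zero (exercising the range branch of the Imp statistic), and the
#' per-condition randomization means two conditions perturbing the same
#' module agree at the module level while their signed gene-level patterns
#' are largely uncorrelated -- drugs rarely reproduce a disease's exact
#' per-gene direction of dysregulation even when they act on the same
#' functional module.
#'
#' @param truth a \code{synthetic_truth} from \code{\link{simulate_ppi}}.
#' @param driver_modules character vector of planted module names carrying
#'   the signal (may be empty: a pure-noise condition).
#' @param effect_size mean absolute perturbation of driver genes
#'   (default 2.5).
#' @param noise_sd standard deviation of the noise (default 0.8).
#' @param seed integer seed, or NULL.
#' @param effect_scale per-driver-module multiplier on
#'   \code{effect_size}: a scalar, or a vector recycled along (or named
#'   by) \code{driver_modules}. Default 1 (all drivers at full strength).
#' @return named numeric gene score vector over \code{truth$genes}.
#' @export
simulate_condition_scores <- function(truth, driver_modules = character(0),
                                      effect_size = 2.5, noise_sd = 0.8,
                                      seed = NULL, effect_scale = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (effect_size < 0) stop("effect_size must be >= 0")
  missing <- setdiff(driver_modules, names(truth$modules))
  if (length(missing))
    stop("unknown driver modules: ", paste(missing, collapse = ", "))
  if (length(driver_modules)) {
    if (is.null(names(effect_scale)))
      effect_scale <- stats::setNames(
        rep_len(effect_scale, length(driver_modules)), driver_modules)
    if (!all(driver_modules %in% names(effect_scale)))
      stop("effect_scale must cover every driver module")
  }
  with_seed(seed, {
    scores <- stats::rnorm(length(truth$genes), 0, noise_sd)
    names(scores) <- truth$genes
    for (m in driver_modules) {
      gs <- sort(truth$modules[[m]])
      signs <- sample(rep(c(1, -1), length.out = length(gs)))
      scores[gs] <- signs * effect_size * effect_scale[[m]] +
        stats::rnorm(length(gs), 0, noise_sd)
    }
    scores
  })
}

#' Simulate a full drug-repositioning benchmark
#'
#' Builds disease and drug gene score vectors plus a benchmark standard on
#' top of a synthetic PPI truth. Each disease is driven by
#' \code{n_driver_modules} planted modules: both members of one planted
#' cross-talk pair (drawn at random per disease) plus further random
#' modules -- encoding the modelling premise that disease-essential
#' modules exhibit mutual cross-talk, so that the module network carries
#' disease-relevant signal. When the truth has no cross-talk pairs, all
#' drivers are drawn at random. Each disease's
#' \code{n_true_per_disease} true drugs perturb exactly its driver
#' modules (with independent noise and signs), while the remaining drugs
#' are decoys:
#' drugs true for other diseases perturb other module subsets, and any
#' leftover drugs alternate between perturbing a random module subset and
#' pure noise. The standard pairs each disease with its true drugs and
#' takes all drugs as the ranking universe.
#'
#' @inheritParams simulate_condition_scores
#' @param n_diseases number of diseases (default 10).
#' @param n_drugs number of drugs (default 60).
#' @param n_true_per_disease true drugs per disease (default 6); the
#'   product with \code{n_diseases} must not exceed \code{n_drugs}.
#' @param disease_attenuation range (min, max) of the uniform per-driver
#'   attenuation applied to \emph{disease} expression only (default
#'   \code{c(0.3, 1)}). Tumour transcriptomes reveal essential modules
#'   only partially -- some driver modules show strong fold-changes while
#'   others are weakly or post-transcriptionally dysregulated -- whereas a
#'   drug perturbation hits its target modules at full strength. The
#'   attenuation reproduces that asymmetry; it is what gives network
#'   propagation something to recover (a weakly expressed driver is pulled
#'   back up by its strongly expressed cross-talk partner). Set to
#'   \code{c(1, 1)} for a fully expressed disease signal.
#' @param n_driver_modules driver modules per disease (default 2: the two
#'   members of one cross-talk pair, a minimal connected disease mechanism
#'   in the module network).
#' @param seed integer seed.
#' @return list with \code{disease_scores} and \code{drug_scores} (named
#'   lists of gene score vectors), \code{standard}
#'   (\code{benchmark_standard}), \code{drivers} (disease -> module
#'   names), \code{true_drugs} (disease -> drug ids) and \code{params}.
#' @export
simulate_benchmark <- function(truth, n_diseases = 10, n_drugs = 60,
                               n_true_per_disease = 6,
                               n_driver_modules = 2,
                               effect_size = 2.5, noise_sd = 0.8,
                               disease_attenuation = c(0.3, 1),
                               seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_true_per_disease > n_drugs)
    stop("n_true_per_disease cannot exceed n_drugs")
  if (n_diseases * n_true_per_disease > n_drugs)
    stop("need n_drugs >= n_diseases * n_true_per_disease")
  if (n_driver_modules > length(truth$modules))
    stop("n_driver_modules exceeds the number of planted modules")
  diseases <- sprintf("DIS%02d", seq_len(n_diseases))
  drugs <- sprintf("DRG%03d", seq_len(n_drugs))

  n_pairs <- nrow(truth$crosstalk_pairs)
  drivers <- with_seed(derive_seed(seed, "drivers"), {
    ds <- lapply(seq_len(n_diseases), function(i) {
      if (n_pairs > 0 && n_driver_modules >= 2) {
        anchor <- truth$crosstalk_pairs[sample.int(n_pairs, 1), ]
        extra <- sample(setdiff(names(truth$modules), anchor),
                        n_driver_modules - 2)
        sort(c(anchor, extra))
      } else {
        sort(sample(names(truth$modules), n_driver_modules))
      }
    })
    names(ds) <- diseases
    ds
  })

  stopifnot(length(disease_attenuation) == 2,
            disease_attenuation[1] > 0,
            disease_attenuation[1] <= disease_attenuation[2])
  disease_scores <- lapply(diseases, function(d) {
    att <- with_seed(derive_seed(seed, "attenuation", d),
      stats::setNames(stats::runif(n_driver_modules,
                                   disease_attenuation[1],
                                   disease_attenuation[2]),
                      drivers[[d]]))
    simulate_condition_scores(truth, drivers[[d]], effect_size, noise_sd,
                              seed = derive_seed(seed, "disease", d),
                              effect_scale = att)
  })
  names(disease_scores) <- diseases

  n_true_total <- n_diseases * n_true_per_disease
  true_drugs <- lapply(seq_len(n_diseases), function(i)
    drugs[((i - 1) * n_true_per_disease + 1):(i * n_true_per_disease)])
  names(true_drugs) <- diseases

  drug_scores <- lapply(seq_len(n_drugs), function(j) {
    dseed <- derive_seed(seed, "drug", drugs[j])
    if (j <= n_true_total) {
      d <- diseases[(j - 1) %/% n_true_per_disease + 1]
      simulate_condition_scores(truth, drivers[[d]], effect_size,
                                noise_sd, seed = dseed)
    } else if ((j - n_true_total) %% 2 == 1) {
      decoy_mods <- with_seed(derive_seed(seed, "decoy", drugs[j]),
        sort(sample(names(truth$modules), n_driver_modules)))
      simulate_condition_scores(truth, decoy_mods, effect_size, noise_sd,
                                seed = dseed)
    } else {
      simulate_condition_scores(truth, character(0), effect_size,
                                noise_sd, seed = dseed)
    }
  })
  names(drug_scores) <- drugs

  pairs <- do.call(rbind, lapply(diseases, function(d)
    data.frame(drug_id = true_drugs[[d]], disease_id = d,
               stringsAsFactors = FALSE)))
  list(disease_scores = disease_scores,
       drug_scores = drug_scores,
       standard = benchmark_standard(pairs, drug_universe = drugs),
       drivers = drivers,
       true_drugs = true_drugs,
       params = list(n_diseases = n_diseases, n_drugs = n_drugs,
                     n_true_per_disease = n_true_per_disease,
                     n_driver_modules = n_driver_modules,
                     effect_size = effect_size, noise_sd = noise_sd,
                     disease_attenuation = disease_attenuation,
                     seed = seed))
}
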
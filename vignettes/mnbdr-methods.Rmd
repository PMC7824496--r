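---
title: "Module-network drug repositioning: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module-network drug repositioning: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnbdr)
```

# The problem and the model

Connectivity-map drug repositioning matches a disease's differential
expression signature against drug perturbation profiles to rank candidate
drugs. Classic scores (KS, Zhang, XSum) operate gene by gene and therefore
assume that an effective drug reproduces (or reverses) the disease's exact
per-gene pattern. `mnbdr` instead works at the level of *modules* — dense
clusters in a protein–protein interaction (PPI) network — and of the
*module network*, whose edges are statistically significant cross-talks
(excesses of PPI edges) between module pairs. The modelling premise is
twofold: pathogenesis and drug response are organised around functional
modules rather than individual genes, and modules that cross-talk
reinforce each other's involvement in disease.

The pipeline:

1. **Module detection.** Vertices of the confidence-filtered PPI graph are
   weighted by `k * density` of the highest k-core of their closed
   neighbourhood (the MCODE weighting). Scanning vertices by decreasing
   weight, each unassigned vertex seeds a cluster that admits unassigned
   neighbours whose weight is at least `(1 - node_score_cutoff)` times the
   seed weight, recursively; a haircut then trims the cluster to its
   2-core; clusters of fewer than 5 proteins are dropped.
2. **Module network.** For every module pair the number of inter-module
   PPI edges is compared with a null distribution obtained by drawing 1000
   pairs of disjoint uniform random node sets of matching sizes from the
   graph's node universe. Pairs with one-sided `p < 0.01` become
   cross-talk edges; modules without a significant partner remain as
   isolated nodes.
3. **Module importance (Imp).** A gene-level signed score vector `F`
   (log2 fold-changes for a disease, z-scores for a drug) is mapped to
   module space by
   `Imp = Fmax - Fmin` if `Fmax > 0 > Fmin`, else
   `Imp = max(|Fmax|, |Fmin|)`,
   with `Fmax`/`Fmin` the extremes of `F` over the module's measured
   genes. The statistic is the score *range* when the module is perturbed
   in both directions and the largest absolute perturbation otherwise.
4. **Propagation (diseases only).** With `W` the column-normalized
   adjacency of the module network and `P0` the disease's Imp vector,
   `P_k = lambda * W %*% P_{k-1} + (1 - lambda) * P0` is iterated to its
   fixed point. The damping factor `lambda = 0.85` (the typical PageRank
   value) balances network smoothing against the expression prior. Drug
   Imp vectors are *not* propagated: a drug perturbation is a direct
   molecular readout, not a partially observed disease state.
5. **Drug scoring.** The disease contributes its ordered top-`n` modules
   (default `n = 15`); the drug's full module list is ranked by raw Imp.
   With `V(i)` the drug-side Imp of the disease's i-th module and `P(i)`
   its position in the drug ranking, the NDCG-inspired indicator is
   `S = sum_i V(i) / (|P(i) - i| + 1)`. Drugs are ranked by descending
   `S`. Note these are perturbation-*overlap* semantics: the sign of the
   drug's effect relative to the disease is deliberately not modelled.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_confidence` | 770 | STRING-style confidence filter (0–1000), inclusive |
| `min_size` | 5 | smallest retained module (proteins) |
| `node_score_cutoff` | 0.2 | admission slack during seed growth (fraction of seed weight) |
| `haircut` | TRUE | trim clusters to their 2-core |
| `alpha`, `n_perm` | 0.01, 1000 | cross-talk significance threshold and permutation count |
| `lambda` | 0.85 | damping factor, fraction of mass propagated per step |
| `tol`, `max_iter` | 1e-9, 1000 | L1 convergence threshold and iteration cap |
| `top_n` | 15 | disease modules entering S (about 10% of a ~120-module network) |
| `n_up`, `n_down` | 100 | signature sizes for the connectivity baselines |
| `extreme_k` | 100 | genes kept per extreme by XSum |

Rank robustness to `lambda` is a property of the method (and is verified
on synthetic data: Spearman correlation of disease module rankings across
`lambda` in 0.5–0.95 exceeds 0.8), so downstream results do not hinge on
the 0.85 convention.

# Numerical choices

* **Permutation p-values** use the pseudo-count convention
  `p = (1 + #{null >= obs}) / (1 + n_perm)`, so p is never exactly 0 and
  the test is valid at finite permutation counts; the bare ratio is
  available via `plus_one = FALSE`. No multiple-testing correction is
  applied across module pairs by default (the raw `p < 0.01` rule); a
  Benjamini–Hochberg option exists (`adjust = "BH"`).
* **Per-pair seeding.** Each module pair's null draws use a seed derived
  by hashing the master seed with the sorted module names, making the
  module network reproducible and independent of pair enumeration order,
  and making `p(A, B) = p(B, A)` exact.
* **Dangling modules.** Columns of `W` for isolated modules are replaced
  by the uniform column `1/m` — the standard PageRank repair — so `W`
  stays column-stochastic and total mass is conserved at every iteration.
* **Prior normalization.** `P0` is L1-normalized before iterating, making
  the convergence tolerance scale-free; rankings (all that downstream
  consumes) are invariant to this choice.
* **Tie-breaking** is lexicographic everywhere a ranking is formed
  (vertex seeds, module ranks, drug ranks), so all outputs are
  bit-reproducible.
* **Degenerate inputs.** An all-zero disease prior is an error (there is
  nothing to propagate); modules whose genes are all unmeasured get
  `Imp = 0` so the module vector keeps a fixed length; diseases with no
  positive (or no negative) candidate are excluded from evaluation with a
  warning.
* **AUC0.1** is reported unnormalized: its maximum is 0.1 and its chance
  level 0.005. The benchmark harness also reports a Gaussian tail
  probability from the permutation null's mean and standard deviation
  alongside the empirical p-value, since the empirical value cannot fall
  below `1/(1 + n_perm)` — extremely small published p-values of this
  kind are necessarily parametric, and reporting both surfaces the
  distinction.

# A property of seed growth worth knowing

With the MCODE admission rule, two equally weighted dense clusters joined
by even a single edge merge into one cluster: the far endpoint carries the
same weight as the seed, passes the threshold, and pulls its whole cluster
in. On real PPI networks, heterogeneous weights limit this; on idealized
equal-size planted cliques it is systematic. Two consequences for this
package:

* `detect_modules` on a graph of planted cliques recovers them cleanly
  only when inter-clique edges are absent; the synthetic PPI generator
  therefore confines its Erdős–Rényi background to gene pairs not
  internal to the planted module set, keeping inter-module connectivity
  under the sole control of the cross-talk parameter and making the
  recovery ground truth unambiguous.
* In the end-to-end synthetic benchmark the ranking and scoring stages
  run on the *planted* module set, supplied as an external module set
  (GMT input is a first-class path through the pipeline): running
  detection there would merge each planted cross-talk pair into one
  cluster and erase the very network being studied. Detection quality is
  assessed separately, on cross-talk-free graphs.

# What the synthetic generator emulates — and what it does not

`simulate_ppi` plants `n_modules = 12` disjoint 8-cliques, connects
`n_crosstalk_pairs = 6` disjoint module pairs by Bernoulli(0.25) bipartite
edges, and adds an Erdős–Rényi background (600 extra genes, edge
probability 0.005). `simulate_benchmark` builds 10 diseases and 60 drugs
(6 true drugs per disease) with driver effect size `delta = 2.5` and noise
`sigma = 0.8`.

Three generator choices encode the method's own assumptions and deserve
justification:

* **Disease drivers are a cross-talk pair.** Each disease's driver
  modules are the two members of one planted cross-talk pair. The
  propagation stage exists to exploit mutual reinforcement between
  cross-talking disease modules; a disease whose drivers were unrelated
  to the module network would make that stage untestable by
  construction.
* **Signs are conserved at module level only.** Within a driver module,
  each condition (disease or drug) receives an independent balanced
  random assignment of +/- `delta`. Both branches of the Imp statistic
  are exercised, and two conditions acting on the same module agree in
  module space while their signed gene-level profiles are nearly
  uncorrelated — reflecting that a drug engaging a pathway rarely
  reproduces the disease's exact per-gene direction of dysregulation.
  This is precisely the regime in which module features are informative
  and gene-level connectivity scores hover at chance, which is the
  directional pattern reported for real cancer benchmarks.
* **Disease expression is partially attenuated.** Each disease driver's
  effect size is scaled by a Uniform(0.3, 1) factor (drug perturbations
  stay at full strength): bulk tumour transcriptomes reveal essential
  modules incompletely, and a weakly expressed driver is exactly what
  propagation can recover from its strongly expressed partner.

The generator does **not** attempt to mimic STRING's degree distribution
or confidence model, LINCS moderated-z statistics, dose/cell-line
structure, or any gene-identifier mapping. Passing synthetic benchmarks
therefore demonstrates correctness of the machinery and the directional
behaviour of the methods under the stated assumptions — not performance
on real compendia.

# Problem sizes used for validation

The test-suite and the acceptance script run at desk scale, chosen so the
whole validation completes in minutes on one core: PPI graphs of ~700
nodes, module networks of 12–40 modules, 1000 permutations per cross-talk
test, benchmark averages over 10 generator seeds, and 1000-permutation
benchmark p-values. Formula-level checks (Imp, S, KS/Zhang/XSum, AUC)
compare against independent brute-force oracles; propagation is checked
against the direct linear solve of `(I - lambda W) P = (1 - lambda) P0`.

# Known limitations

* Identifiers are opaque strings; harmonizing PPI and expression gene IDs
  is the caller's responsibility.
* The permutation null for cross-talk is node-uniform, not
  degree-matched; hub-rich modules may cross-talk more easily. A
  degree-preserving null is an explicit non-goal.
* Signature reversal (negative connectivity as the therapeutic signal) is
  not modelled; S rewards perturbation overlap, faithfully to the module
  ranking it extends.
* The drug-sample quality filter applied to real LINCS data (expression
  signal strength) is not part of this package; callers should filter
  their drug score vectors before entry.
* Multiple signatures per drug (cell lines, doses) must be merged
  upstream; averaging per drug is the recommended default, taking the
  maximum over signatures a documented alternative.
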
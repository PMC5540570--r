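---
title: "Methods: GGM co-expression networks with ggmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GGM co-expression networks with ggmnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`ggmnet` treats log-scale gene expression as a draw from a multivariate
normal and identifies gene-gene association with the non-zero off-diagonal
entries of the precision matrix $\Omega = \Sigma^{-1}$: the partial
correlation $-\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}$ is the correlation
between genes $i$ and $j$ after removing the linear effect of every other
gene, so edges encode direct (conditional) association rather than the
direct-plus-indirect mixture that Pearson correlation measures.

Three practical obstacles shape the pipeline, and each stage answers one:

* **FPKM values are heteroscedastic** — per-gene variance grows with the
  mean. `log_transform()` applies $\log_2(\text{FPKM}+1)$, which largely
  flattens the dependency (`mean_variance_profile()` quantifies it before
  and after). `filter_low_expression()` first removes genes whose maximum
  FPKM across samples is below 20; such genes carry mostly noise at the
  correlation stage. The threshold is a strict cut: a gene whose maximum
  equals 20 is kept.
* **Genes far outnumber samples**, so the empirical correlation matrix is
  singular. `shrinkage_partial_correlation()` uses the Schafer–Strimmer
  estimator toward the identity target,
  $R^\ast = \lambda^\ast I + (1-\lambda^\ast) R$ with
  $\lambda^\ast = \sum_{i<j}\widehat{\mathrm{Var}}(r_{ij}) \big/
  \sum_{i<j} r_{ij}^2$ clamped to $[0,1]$, estimated from the products of
  standardized observations (the "dynamic" data-driven intensity). With
  $\lambda^\ast>0$ the shrunk matrix is positive definite and invertible
  for any gene/sample ratio.
* **Even shrinkage cannot condition on 20,000+ genes at once**, and a
  single global inversion would be both expensive and unstable.
  `sampled_pcor_estimation()` therefore draws random gene subsets (the
  study-scale plan is 25,000 iterations of 2,000 genes) and aggregates,
  for every pair, the recorded partial correlation of **minimum absolute
  value, sign kept**. The minimum is conservative by design: a pair's
  aggregated Pcor survives only if its direct association persists across
  every conditioning subset in which the two genes met.

Edges are then selected by `select_edges()` where Pcor and PCC agree in
sign and both pass their thresholds (defaults 0.035 and 0.35). The PCC
co-filter removes pairs whose partial correlation is nominally high but
whose marginal correlation is negligible — a pattern more consistent with
conditioning artifacts than with co-expression.

# Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `min_max_fpkm` | 20 | FPKM; per-gene maximum required to keep a gene |
| `n_iterations` × `subset_size` | 25,000 × 2,000 | sampling plan; reduced plans are appropriate below ~1,000 genes |
| `pcor_threshold`, `pcc_threshold` | 0.035, 0.35 | edge admission on aggregated Pcor and log-scale PCC |
| `inflation` | 1.5 | MCL granularity; higher splits finer |
| `min_module_size` | 5 | modules below this are set aside, not numbered |
| `prune_threshold`, `max_per_column` | 1e-6, 1500 | MCL sparsity bounds (large-scale resource control; they do not alter desk-scale fixed points) |

The expected number of times a pair is co-sampled is
$T\,\frac{s}{g}\cdot\frac{s-1}{g-1}$; `sampled_pcor_estimation()` warns
when it drops below 1 and reports the realized pair coverage. Pairs never
co-sampled get Pcor 0 — absence of evidence is treated as absence of an
edge, and the coverage figure makes that visible.

# Markov clustering

`mcl_cluster()` runs MCL on the **unweighted, sign-blind** adjacency with
unit self-loops: modules are a property of the network's topology, not of
edge strength, and self-loops guarantee aperiodic flow. Each iteration
squares the column-stochastic matrix (expansion), raises entries to the
inflation power and renormalizes (inflation), and prunes per column
(drop < 1e-6, keep the 1500 largest, renormalize). Convergence is the
max-norm change between successive matrices (tolerance 1e-8, cap 200
iterations; non-convergence returns the current clustering with a
warning). Clusters are read from the limit matrix's attractors — rows with
positive diagonal — with overlapping attractor systems merged; a gene
reachable from several clusters joins the larger (tie: smaller module id).
Modules are renumbered by descending size, ties broken by smallest member
gene id, so "module 1" is always the largest.

# Enrichment

`go_enrichment()` is a plain one-sided hypergeometric over-representation
test with Benjamini–Hochberg adjustment within each module. It
deliberately does not model the GO graph: annotations are taken as
supplied, and ancestor propagation, if wanted, is the caller's
preprocessing step. `motif_enrichment()` models "promoter contains ≥ 1
match" as a Bernoulli event with universe-wide rate $p_0$ and tests the
module count against Binomial($n$, $p_0$); a per-occurrence alternative
was rejected because it would be confounded by unequal promoter lengths.
`scan_promoters()` counts overlapping IUPAC matches on both strands
(motif against the sequence and against its reverse complement) because
transcription-factor binding is strand-agnostic; ambiguity codes expand
only in the motif, never in the sequence, so an N in a promoter cannot
match.

# Cross-species conservation

`conserved_interactions()` implements the neighborhood rule: gene $g$ is
conserved iff some neighbor of $g$ has a homolog among the neighbors (in
the second network) of some homolog of $g$. Many-to-many homolog pairs are
all honored — the neighbor set B is a union over homologs — leaving any
one-to-one restriction to the producer of the map.
`module_conservation()` reports percentages with **all** module genes in
the denominator by default, including genes without a homolog, because
module-level conservation is a statement about the module, not about its
mappable subset; `homologs_only = TRUE` switches the denominator for
sensitivity analysis.

# Module profiles and network evaluation

`module_mean_expression()` averages log2(FPKM+1) values over a module's
genes and a group's samples, pooling all samples within a group, and
reports each module row relative to its maximum (an all-zero row stays
zero rather than dividing by zero). Log-scale averaging is the default
because the profiles feed relative-to-max comparisons, which the raw
scale's heavy tails would distort; `require_log = FALSE` allows raw-scale
profiles. `neighbor_voting_auroc()` scores each gene of degree ≥ 1 by the
fraction of its neighbors inside a gene set (leave-one-out, no fold
partition — same ranking semantics as cross-validated neighbor voting at
this scale, without fold nondeterminism) and summarizes with a mid-rank
AUROC that is exactly the pairwise-comparison probability.

# The synthetic generator: what it emulates, what it does not

`generate_planted_model()` plants modules as **ring-plus-chords**
conditional-dependence patterns (default chords: half the module size,
mean within-module degree ≈ 3). A full-clique precision block would need
entries of order $1/m$ to stay positive definite, washing out the signal;
the sparse pattern keeps planted partial correlations at a realistic
magnitude (default 0.3). Positive definiteness is enforced by adding
$\delta I$ with $\delta = \max(0, 10^{-3} - \lambda_{\min})$, reported via
a message; the repair shrinks planted partial correlations by
$1/(1+\delta)$, typically well under 10%.

`simulate_expression()` draws latent Gaussians with the planted precision,
gives each gene a base mean (uniform on log2 FPKM 3–8 — the range typical
of genes that pass a max-FPKM-20 filter in bulk compendia) and scale
(uniform 0.6–1.2), and maps through $2^z-1$ clipped at 0 — the exact
inverse of the preprocessing transform, so the pipeline's log step
recovers the latent scale, while the raw scale exhibits the mean-variance
dependency real FPKM data show. The generator does **not** emulate read
counts, library-size or batch effects, multi-study composition, or
dropout; passing tests demonstrate correctness of the estimators on data
satisfying the model's assumptions, not robustness to those artifacts.

Annotation, promoter, and conservation generators plant known signal
(marker terms at 80% of a module vs 5% background; one motif instance per
implant gene; relabeled partner networks with controllable rewiring) so
that every downstream statistic can be checked against its planted truth.
All generators are pure functions of their arguments and seed; stage and
iteration seeds are derived by stable hashing, so results are independent
of execution order and adding a stage never perturbs another's stream.

# Numerical and design choices

* Aggregation ties in `|Pcor|` (including opposite signs) keep the
  earliest iteration's value, making aggregation deterministic.
* Constant genes yield zero partial correlations and zero PCC with a
  warning, not an error, so a single flat gene cannot abort a long run.
* Mean-rank ties in `mean_variance_profile()` break by gene id; the trend
  is a running median over a centered 301-rank window, clipped at the
  boundaries (any robust centered smoother would do; the width is a
  parameter).
* `random_expected_clustering()` returns the Erdős–Rényi edge probability
  $2E/(N(N-1))$, the expected transitivity of a random graph of identical
  size; the package fixes global transitivity (not mean local clustering)
  as its clustering coefficient, which is the definition comparable to
  that expectation.
* Whether PCC is computed before or after Pcor aggregation does not change
  the selected edge set; selection is applied last. PCC is computed on the
  log scale, the same scale the GGM sees.
* Test and acceptance runs use reduced problem sizes chosen for quick
  iteration at desk scale: edge recovery at 200 genes × 400 samples with
  200 iterations of 80-gene subsets, and end-to-end module recovery at 40
  planted modules × 20 genes, 400 samples, 300 iterations of 200-gene
  subsets with relaxed thresholds (Pcor 0.05, PCC 0.2). Relaxation is
  needed because the min-absolute aggregation over a reduced iteration
  count attenuates Pcor magnitudes relative to the 25,000-iteration study
  scale.

# Known limitations

* The shrinkage variance estimator is the standard dynamic one; exact
  numeric agreement with any specific implementation of the same estimator
  is not a goal.
* MCL pruning bounds are fixed resource controls, not the adaptive
  pruning schemes of the standalone `mcl` binary; bit-identical output on
  large graphs is out of scope.
* Hypergeometric enrichment without GO-graph decorrelation overstates
  significance for correlated ancestor terms if annotations are
  propagated; interpret adjusted p-values within that limit.
* Conservation percentages depend on homolog-map quality; the package
  consumes the map and cannot detect mapping errors.
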
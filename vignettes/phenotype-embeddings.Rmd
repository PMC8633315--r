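---
title: "Encoding, embedding and evaluating phenotype profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding, embedding and evaluating phenotype profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenospace)
```

## The problem

Mouse models and human diseases are described by *phenotype profiles*:
sets of terms from a hierarchical vocabulary (an is-a DAG such as the
mammalian phenotype ontology). Profiles are sparse — most entities carry
a handful of terms out of thousands — and the terms are not independent,
because annotating "increased heart weight" logically implies "abnormal
heart weight" and, further up, a cardiovascular phenotype. This package
provides the machinery to (i) turn such profiles into comparable numeric
or text representations, (ii) map a cohort into a low-dimensional space
for exploration, and (iii) quantify how much the representations and
maps preserve, using neighbor-based prediction, enrichment, same-gene
statistics and disease–gene recovery.

## Representations

**Ancestor-closed binary vectors.** `encode_binary()` sets `v_t = 1`
exactly on the reflexive ancestor closure of the annotated set. Closure
makes logically implied annotations explicit and is idempotent; it is
the only inference the package performs on the ontology (no OWL
reasoning, is-a edges only).

**Bayesian real-valued vectors.** `encode_nonbinary()` combines three
information sources:

1. *the cohort*: every term starts at its prior
   `p_t = (n_t + α) / (N + 2α)`, where `n_t` counts profiles whose
   closed annotation set contains `t`. Counting closed sets makes
   priors monotone along edges by construction. The pseudocount
   (default `α = 1`) keeps every prior strictly inside (0, 1), which
   the Bayesian update requires; with an empty cohort all priors are
   1/2, an honest "no information" state.
2. *the annotations*: a directly annotated term is treated as a
   positive detection with true-positive rate `tpr` and false-positive
   rate `fpr`, giving the posterior
   `p·tpr / (p·tpr + (1−p)·fpr)`. Defaults `tpr = 0.8`, `fpr = 0.05`
   encode the view that curation is strong but imperfect evidence;
   any values with `tpr > fpr > 0` are accepted, and `tpr ≤ fpr`
   (annotation uninformative or contradictory) is rejected.
3. *the hierarchy*: values are max-propagated toward the roots in
   reverse topological order, so `v_parent ≥ v_child` holds on every
   edge and each value never falls below its prior.

The propagation rule was a genuinely open design point: the outline
(priors, Bayesian update, hierarchical propagation) admits several
concrete schemes. Max-propagation was chosen because it preserves the
edge-monotonicity invariant exactly, is order-independent, and reduces
to the binary encoding in the sharp-evidence limit (`tpr → 1`,
`fpr ≪ p_t → 0`); the test suite checks all three properties. Averaged
predictions are *not* renormalized (a "simple average"), so prediction
errors are comparable across neighbor sources.

**k-mer text bags.** `kmerize()` lowercases, maps non-alphanumerics to
spaces, and takes overlapping character k-mers per token (short tokens
kept whole). The default `k = 6` balances specificity against sparsity
for short phenotype names; it is configurable everywhere. Weights are
smoothed inverse document frequencies, `ln((D+1)/(df+1)) + 1`, strictly
positive and defined for unseen k-mers (`ln(D+1) + 1`), and similarity
is the weighted cosine. The corpus is user-supplied; ontology term
texts themselves are a reasonable desk-scale corpus — absolute
similarities shift with the corpus but every ranking-based contract is
unchanged. Cross-ontology term mapping (`map_term()`) keeps only the
single best hit, with ties broken by smallest term id; diffusion-style
query expansion is deliberately out of scope.

## Neighbors and embeddings

All neighbor computations are exact brute-force searches with
deterministic tie-breaks (distance, then entity id); there is no
approximate index. Encoded rows are unit-normalized first, so Euclidean
distance is rank-equivalent to cosine similarity. Distances are
computed from explicit row differences rather than the Gram-matrix
identity: the cancellation-free form guarantees duplicated profiles sit
at exactly zero distance, which the zero-error prediction invariant
relies on.

`embed_nonlinear()` is a UMAP-family manifold layout implemented in the
package (R + a small C++ optimizer):

- the precomputed exact neighbor lists are converted to a fuzzy graph
  with per-entity bandwidths calibrated so memberships sum to
  `log2(k)`, then symmetrized with the probabilistic t-conorm;
- the low-dimensional kernel `1/(1 + a d^{2b})` is fitted by
  least squares from `min_dist` and `spread`; the default
  `min_dist = 0.2` spreads adjacent points for readable scatter
  layouts;
- initialization is spectral (normalized-Laplacian eigenvectors) with
  tiny seeded jitter, and the layout is optimized by stochastic
  gradient descent with negative sampling (300 epochs, 5 negative
  samples per positive).

Because neighbors are exact and precomputed, the usual stochasticity of
approximate neighbor search is absent, and the optimizer uses its own
seeded integer random stream — the same inputs and seed therefore give
bit-identical coordinates on any platform, a property the test suite
asserts. Repeating an embedding under two seeds and comparing 15-NN
Jaccard sets (`neighbor_jaccard()`) is the supported stability check.

`embed_linear()` is PCA of the row-centered matrix with component signs
fixed by the largest-magnitude loading, making it fully deterministic;
at full rank it is an isometry of the centered data (tested to 1e-9).

**Projections and their bias.** Term sets can be projected into a term
embedding by coordinate averaging (`project_terms_average()`). Averaging
`n` roughly independent coordinates shrinks the result toward the
global centroid like `1/sqrt(n)`, so richly annotated profiles are
systematically pulled centerward. `center_bias()` quantifies this with
the Spearman correlation between annotation count and distance to the
centroid ("center" = centroid of the projections; the origin is an
arbitrary alternative and was not used). This bias is the reason
profile-level embeddings, not term-level embeddings plus averaging, are
the recommended visualization route. Diseases are placed in a model
embedding either at the mean of their `k` nearest models
(`project_disease_vector()`; optimizer-based refinement of the initial
placement is intentionally not applied, keeping the contract simple
and backend-free) or at the single most text-similar model
(`project_disease_text()`).

## Evaluation procedures

**Prediction and k calibration.** `calibrate_k()` predicts each entity
as the plain average of its `k` nearest neighbors' non-binary rows and
scores the L2 error against the entity's own row — a self-supervised
criterion needing no ground truth. The grid default is `k = 1..20`,
with ties resolved toward the smaller `k` (the simpler predictor).
Errors are always measured against the non-binary matrix regardless of
where neighbors came from, so curves from the original space and from
embeddings of any dimension share a scale.

**Enrichment.** `fisher_enrichment()` compares ancestor-closed
annotations inside a region (an explicit id set, or a rectangle via
`region_from_rectangle()`) against the rest of the cohort with
two-sided Fisher exact tests. The tested family is the set of terms
with at least one in-region closed annotation — terms absent from the
region are untestable and would only inflate the Bonferroni family
size. Significance is `p ≤ α/m` at family level `α = 0.05`.

**Same-gene consistency.** For models whose gene has `m ≥ 2` models in
a cohort of `N`, the probability that `k` random neighbors contain a
same-gene model is `1 − C(N−m, k)/C(N−1, k)`; `same_gene_neighbor_
fraction()` reports observed fractions against this null, stratified by
multiplicity, at `k = 15` by default (the same depth used for
embedding-consistency Jaccard and disease matching).

**Disease–gene recovery.** `gene_recovery_at_k()` scores a disease as a
hit when any of its `k = 15` nearest models carries a causal gene.
Only diseases with both phenotype terms and causal-gene labels are
evaluable. The baseline (`gene_recovery_permuted()`) shuffles
causal-gene labels across diseases while keeping all neighbor lists
fixed. Note a structural floor on any such baseline: if the 15 nearest
models of a typical disease span `g` distinct genes, a random label
hits with probability about `g / n_genes`; with realistic gene
multiplicities near 3, `g` is around 10, so at 50 genes the permuted
baseline sits near 0.2 rather than near zero. Planted recovery well
above that floor, not the floor's absolute size, is the meaningful
signal.

## The synthetic generator

`synthetic_config()` fixes the study conditions; every generated object
is a deterministic function of the seed, and generators restore the
caller's RNG state.

- *Ontology*: a breadth-first tree (branching 3) over `n_terms` terms;
  each non-root term gains a second parent with probability 0.08,
  drawn among earlier-created terms so acyclicity holds by
  construction. Names inherit one syllable token from the tree parent,
  so lineage-related terms share text — this is what gives the k-mer
  engine a planted signal.
- *Cohort*: gene multiplicities follow a truncated power law
  `P(m) ∝ m^−1.5`, `m ≤ 20` (mean ≈ 3), matching the models-per-marker
  ratio of large curated mouse cohorts (roughly 54k models over 16k
  markers). Signatures are sampled leaf-biased (weight
  `1/(1 + #descendants)`), because real curation favors specific
  terms — that is precisely what makes ancestor closure informative.
  Signature *sizes* are 1 + geometric with mean `signature_size = 8`,
  and models keep each signature term with probability 0.8 plus
  Poisson(1) random extras; the geometric sizes are what produce the
  strongly right-skewed annotation-count distribution seen in real
  cohorts, and the skew (median < mean) is asserted by test.
- *Diseases*: one causal gene each; terms are the gene's signature at
  retention 0.8 plus Poisson noise, with a 5% chance of replacing a
  kept term by a sibling — a cheap stand-in for cross-ontology
  translation error that stays entirely in the target ontology.

What the generator does **not** emulate: pleiotropy shared across
genes, correlated annotation sources, frequency-of-onset or negated
annotations, realistic ontology depth imbalance, and real text styles.
Tests passing on synthetic cohorts therefore demonstrate the
*machinery* (contracts, invariants, orderings), not performance on any
real database release.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as
the smallest sizes at which the studied effects are stable:
500-term ontologies; cohorts of ~180 genes (≈ 650 models) for the
embedding-fidelity comparisons, replicated over 10 seeds with majority
voting; 2 000 projection draws with 1–50 terms for the center-bias
diagnostic; 200 diseases over 50 genes for recovery; 10⁴ draws for
Monte-Carlo nulls. Fisher p-values are validated against exact
hypergeometric enumeration for all 2×2 tables with margins up to 30
(tolerance 1e-10). Degenerate inputs have defined behavior throughout:
zero vectors refuse normalization naming the entity, empty regions and
all-identical counts raise typed errors or NA-with-warning, k is
clipped with a message when it exceeds the cohort, and empty text
queries return empty results with a warning.

## Known limitations

- The nonlinear layout is a compact implementation tuned for cohorts of
  order 10³–10⁴, not 10⁶; the spectral initialization uses a dense
  eigendecomposition.
- Only is-a edges are honored; ontologies whose semantics depend on
  other relationship types are flattened (a warning is emitted once).
- Obsolete terms are dropped at parse time; annotations referencing
  them must be remapped upstream.
- The text engine does no stemming and is monolingual by construction;
  it is intended for ontology-style technical English.
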
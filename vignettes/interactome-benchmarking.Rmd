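---
title: "Benchmarking molecular interaction networks with netbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking molecular interaction networks with netbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netbench)
library(dplyr)
```

## The problem

Dozens of gene and protein interaction networks — yeast-two-hybrid screens,
affinity-purification complexes, literature-curated pathway databases,
co-expression and functional-association compendia — all claim to describe
the human interactome, yet they disagree substantially in coverage, in
which genes they emphasize, and in how useful they are for downstream
inference. netbench provides the machinery to benchmark any such
collection on equal footing: standardize the networks, quantify their
representation biases, score how well each one recovers known gene sets
through network propagation, combine the best performers into consensus
networks, and evaluate how well network topology predicts new
interactions.

Everything operates on tabular data: an interactome is a tibble of
canonical undirected edges over integer gene identifiers (NCBI Gene IDs by
convention), and every analysis returns a tibble, so results chain with
the usual dplyr verbs.

## Standardization

All inputs pass through one normalization: self-interactions removed,
records with more than two members expanded to all pairwise edges,
directions dropped, duplicates collapsed (keeping the maximum score when
scores conflict — the strongest-evidence rule; the choice matters only for
scored sources and is deliberately conservative). Edges are stored in
canonical `(min, max)` order, which makes edge-set operations — Jaccard
overlap between networks, support counting across a corpus — exact set
arithmetic. The node set is implied by the edge list, so a gene belongs to
a network only if it has at least one interaction; genes isolated by
filtering disappear. Very large scored sources are trimmed with
`filter_top_fraction()` (the `ceiling(f * |E|)` highest-scoring edges,
ties broken by score then lexicographic edge order, so the cut is
deterministic without randomness).

## Gene-set recovery

The central benchmark asks: if part of a coherent gene set is hidden, does
the network's wiring point back to it? For a gene set with `n` members in
the network:

1. A fraction $\rho$ of the members is drawn without replacement as seeds
   (count `round(rho * n)`, clamped so both seeds and holdout are
   non-empty).
2. Seed signal diffuses by random walk with restart, using the closed form
   $F = (1-\alpha)\,F_0\,(I - \alpha A_{norm})^{-1}$ with the symmetric
   normalization $A_{norm} = D^{-1/2} A D^{-1/2}$. The symmetric form is
   chosen because its spectral radius is at most 1, so the inverse exists
   for every $\alpha < 1$; `propagate_iterative()` provides the power
   iteration as an independent numerical route, and the two agree to
   near machine precision in the tests.
3. All non-seed network genes are ranked by propagation score and the
   AUPRC for recovering the holdout is computed in its average-precision
   form (mean precision at each positive's rank). Before the stable sort,
   gene order is randomly permuted with the sample's own RNG stream, so
   tied scores cannot systematically favor low identifiers.
4. Steps 1–3 repeat over `n_samples` subsamples; the mean AUPRC is the
   observed performance.

Raw AUPRC is not comparable across networks — it rises with density and
with the degree of the set's genes. The null model therefore rewires the
network by degree-preserving double-edge swaps (`10 |E|` attempted swaps
through igraph's C implementation), recomputes the mean AUPRC on `n_null`
such rewired networks, and scores the observation as a robust Z:
$(obs - \mathrm{median}(null)) / (c \cdot \mathrm{MAD})$. The MAD
consistency constant defaults to $c = 1.4826$ so that on Gaussian nulls
the robust Z matches the classical z-score; `c = 1` is available for the
raw-MAD convention, since sources differ on this point. The performance
gain $(obs - \mathrm{median}) / \mathrm{median}$ is the complementary
relative measure. The shuffled replicates are generated once per network
and shared by all gene sets, which is both the cheaper and the
conceptually right structure: the null describes the network, not the
gene set.

Two corrections make scores comparable across a panel: per-gene-set OLS
residuals of Z on `log10(|E|)` (size-adjusted performance), and
centralized ranks, `rank - (m+1)/2`, which sum to zero however many of the
`m` networks could be evaluated for a given set — so small sets evaluable
only on large networks do not distort the overall ordering. The overall
network score is the mean of its centralized ranks (lower is better).

### Parameters

$\rho$ and $\alpha$ default to fitted linear formulas in network size
`S = log10(|E|)` and gene-set coverage `C`:
$\rho = 0.44 + 0.0093 S - 0.0013 C$ clamped to $[0.1, 0.8]$, and
$\alpha = 0.59 + 0.24\bar\rho - 0.058 S + 0.00036\bar C$ clamped to
$[0.2, 0.9]$. The coefficients are constants of the tool, fitted upstream
on an independent pathway collection; refitting them is out of scope. The
normalizations behind `S` and `C` are interpreted here as the raw
`log10` edge count and the raw intersection size. Fixed values (e.g.
$\rho = 0.3$, $\alpha = 0.64$, the mean-optimal convention for composite
networks) can be passed directly.

## Representation biases

`permutation_median_test()` asks whether a network's genes have unusually
high annotation values (citations, expression, abundance, conservation)
by comparing the observed median to medians of equal-size random samples
from the background; the test is one-sided for enrichment with a strict
"greater than" comparison, the p floors at `1/n_perm` when no permutation
exceeds the observation, and the q multiplies by the number of networks
tested (Bonferroni). `interaction_density()` normalizes interaction
counts between annotation bins by possible pairs: diagonal cells use
$\binom{|A|}{2}$; off-diagonal cells use $|A||B|/2$ exactly as specified,
which admits densities above 1 off-diagonal — the convention is kept
verbatim and documented rather than corrected, because the matrix is used
as a relative measure. For overlapping term-based bins the denominator
switches to the count of unique unordered cross-bin pairs, which is the
only interpretation that accounts for shared genes without double
counting.

Expression profiles are classed by the Human Protein Atlas rules (low /
tissue-enriched / group-enriched / tissue-enhanced / broad, in that
precedence). The group-enriched search is greedy over tissues sorted
descending — the first group of 2–7 whose minimum is fold-times every
non-group tissue wins. A greedy scan is not guaranteed to find every
qualifying group, but with a multiplicative fold criterion on sorted
values the first qualifying cut is the canonical one, and this matches
how the classification is applied in practice.

## Consensus composites

`count_edge_support()` indexes every interaction by how many corpus
networks contain it. Global composites keep edges with support at least
`k`; ranked composites count support only among the top-`k` networks of a
performance-ranked list and keep edges with support at least `m`. The
ranking is an explicit input — typically `benchmark_recovery()`'s overall
centralized rank on size-adjusted scores — rather than something the
composite step recomputes. Named presets (`PCNet2.0`: k=15, m=2;
`PCNet2.1`: k=8, m=2, capped at two million edges kept
highest-support-first with lexicographic ties; `PCNet2.2`: k=10, m=2 over
a co-citation-free ranking) reproduce the published construction rules;
applied to a user corpus they of course yield that corpus's composites,
not the published networks.

## Interaction prediction

Two purely topological predictors are implemented. L3 scores a candidate
pair by its degree-normalized count of length-3 paths,
$\sum_{U,V} a_{XU} a_{UV} a_{VY} / \sqrt{k_U k_V}$, computed for all
pairs at once as the sparse product $A D^{-1/2} A D^{-1/2} A$ and verified
in the tests against explicit path enumeration. MPS ranks candidates by
maximum neighborhood-Jaccard similarity (the best match between one
endpoint and the other endpoint's interactors, summed over both
directions) with preferential attachment (degree product) as the
secondary key; the primary/secondary ordering is a documented choice
consistent with the method's similarity hypothesis, with lexicographic
edge order as the final deterministic tie-break. Candidates with an
isolated endpoint are skipped, since neighborhood similarity is undefined
for them.

Evaluation is precision@k. In 10-fold cross-validation each fold's
candidates are scored on the 90% training graph and `k` equals the
evaluable test-set size — held-out edges whose endpoint loses all its
training edges are excluded from both `k` and the positives, because no
topological method can predict around a degree-zero node. Against
external positive sets (complex- or pathway-derived edge lists), edges
already in the network and edges with absent endpoints are excluded and
`k` is the remaining positive count. Top-`k` selection uses a partial
sort on the score keys so the full quadratic candidate space is never
ordered.

## Assemblies and structure scores

Externally detected communities (e.g. from hierarchical community
detection) are consumed as flat files and scored three ways: recovery of
reference complexes at set-Jaccard ≥ 0.5; a functional-coherence score
summing pairwise per-branch semantic similarities over all member pairs,
scaled by 1/3 — as a pair-summed total it grows with community size, so
the per-pair mean is always reported alongside; and the mean local
clustering coefficient on the community-induced subgraph (members missing
from the network contribute 0). The induced subgraph is used, rather than
neighborhoods in the full network, because assemblies are evaluated as
standalone structures; both scores are skipped for communities of 200 or
more genes, where quadratic pair sums stop being informative. Semantic
similarity is an injected provider function — term-overlap and
Jaccard-over-terms reference providers ship with the package — so no
ontology dependency is pinned.

Structure-model score records (ipTM/pTM per model, externally produced)
are aggregated by model confidence $0.8\,ipTM + 0.2\,pTM$, keeping the
best model per pair (ties to the lowest model id). The structural-support
threshold is always derived from a supplied background distribution — the
95th percentile with linear interpolation between order statistics — and
never hard-coded, because a percentile cutoff is meaningful only relative
to its own background sample. Group-vs-background comparisons use the
two-sided Mann–Whitney U test with BH correction, appropriate for the
strongly right-skewed score distributions.

## Synthetic data and what the tests show

`generate_network()` (Erdős–Rényi and heavy-tailed power-law models),
`plant_module()` (a densified subgraph with known membership),
`generate_gene_sets()` (planted truth, uniform random, and degree-matched
random draws), `generate_annotations()` (annotation values with a
controlled rank correlation to degree, via a Gaussian copula), and
`generate_af_background()` (right-skewed beta scores) produce every input
the pipeline consumes, bit-reproducibly under a seed. The default scale —
1000 nodes, ~10,000 edges, modules of ~25 genes at 10× background
density, 10 subsamples and 10 nulls per cell — keeps a full benchmark
replicate in seconds while leaving planted signal unambiguous; the
recovery calibration runs 20 such replicates.

Synthetic networks emulate the degree heterogeneity and modular structure
that drive the benchmark's statistics, and the annotation generator
emulates the degree–citation confounding the representation tests
measure. They do not emulate the literature-driven dependence structure
between real networks, assortativity patterns, or biologically meaningful
community hierarchy. Passing tests therefore demonstrate that the
machinery is correct and calibrated — nulls centered, planted signal
recovered, oracles matched — not that any particular real interactome
ranks anywhere.

## Numerical choices and edge cases

* Propagation uses a sparse direct solve with all subsample seed vectors
  as one multi-RHS system; the iterative route exists for operators too
  large to factor and must agree to 1e-8 where both run.
* Empirical permutation p-values use strict `>` and floor at `1/n_perm`;
  a zero-MAD null yields a signed-infinity Z with a warning rather than a
  silent division; a zero null median leaves the gain undefined.
* All RNG flows from one master seed through arithmetic substreams, so
  any single (network, gene set, replicate) cell reproduces in isolation.
* Degenerate inputs fail loudly: empty networks cannot be normalized,
  gene sets need two network members, size adjustment refuses equal-size
  panels, rankings with k = 0 are errors.

## Known limitations

Support counting treats corpus networks as independent witnesses; shared
provenance between sources inflates support and is not modeled. The
off-diagonal density convention above can exceed 1. MPS scoring is
quadratic in candidate count and is the practical bottleneck on dense
networks. The parameter formulas extrapolate outside the network sizes
they were fitted on, which the clamps only partially mitigate.
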
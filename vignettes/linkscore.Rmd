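---
title: "Methods and modelling choices in linkscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in linkscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkscore)
```

## The problem

Real interaction networks are observed incompletely: protein–protein
interaction screens miss true interactions, co-authorship and communication
records lag behind reality, web crawls truncate. Because the topology of
such networks is far from random, the observed part carries information
about the unobserved part. *Link prediction* exploits this: every absent
node pair (a *non-edge*, or negative link) receives a score, and high-scoring
pairs are proposed as missing or future links. This package implements the
complete workflow — graph storage tuned for non-edge enumeration, local
similarity indices, graph-embedding predictors, and the evaluation protocol
standard in this literature — in one consistent, seeded, testable API.

## The network container

A network is built in two phases. Before `assemble()`, nodes (by text label)
and edges (by 0-based ID) can be added; after it, the graph is immutable and
queryable. This mirrors how the data structures are actually used: all
predictors assume a frozen adjacency, and freezing it once lets adjacency be
stored as sorted integer vectors with `O(log k)` membership tests and a
precomputed non-edge index.

IDs are contiguous `0, …, n−1` in insertion order. We deliberately expose
0-based IDs (against R convention) because the contiguity contract — ID
equals position in insertion order, degrees and codes indexable by ID — is
easier to state and test this way; every data-frame output also carries the
text labels.

**Non-edge enumeration.** The `n(n−1)/2 − m` absent canonical pairs are
ordered lexicographically. For each source `i` we store the count of absent
partners `j > i`; prefix sums of these counts let a global index be decoded
with a binary search plus a scan over `i`'s higher neighbors, i.e. without
ever materializing the set. Sampling draws indices uniformly and decodes
them, so a sample of non-edges costs memory proportional to the sample, not
to `n²`. Self-loops are rejected at insertion and duplicate edges collapse
silently: the model is a simple undirected graph, and those are the simplest
semantics consistent with it.

## Distances and landmarks

Dijkstra's algorithm runs over an edge-length map (all lengths 1 by
default, in which case distance equals hop count — an invariant the tests
enforce). The exact pairwise calculator caches single-source rows under two
strategies, `full` (keep everything) and `lru` (bounded rows), because
all-pairs tables are the memory bottleneck on large networks.

The approximate calculator picks a landmark set `L`, precomputes exact rows
from each landmark, and estimates `d(i,j) ≈ min_{k∈L} [d(i,k) + d(k,j)]`.
By the triangle inequality this never underestimates, and it is exact
whenever some landmark lies on a shortest `i–j` path; with `L = V` the `k=i`
term makes it exact everywhere. Landmarks default to the highest-degree
nodes (ties broken toward lower IDs) since hubs lie on many shortest paths;
any explicit set can be supplied. Hop counts attached to approximate
distances are the sum of the two legs at the minimizing landmark (lowest
landmark ID on ties) and are themselves approximate; unreachable pairs are
reported as `Inf` rather than as errors so that calculators compose with
predictors on disconnected observed networks.

## Topological similarity indices

All local indices are functions of the common-neighbor set
`C = N(i) ∩ N(j)` and degrees. Two conventions needed fixing:

* **Adamic–Adar** uses the natural logarithm. A common neighbor always has
  degree ≥ 2, so `ln k_z > 0` and the index is well defined.
* **The local-community resource-allocation variant** (Cannistraci-style) is
  defined here as `sum_{z∈C} |N(z) ∩ C| / k_z`: each common neighbor is
  weighted by how strongly it connects *back into* the local community `C`.
  Several normalizations circulate in the literature; this one reduces to
  resource allocation when every common neighbor has exactly one link into
  `C`, and is the definition the test oracle implements independently.

Ties are ubiquitous with integer-valued indices, so every ranking operation
(top-k, top-precision) orders by score descending, then lexicographic
canonical pair. This makes rankings total and reproducible, which the
sort-and-truncate equivalence tests rely on.

## Embedding predictors

Three encoder families cover the spectral, factorization and random-walk
approaches:

* **Laplacian eigenmaps** solves `L y = λ D y` and keeps the `d`
  eigenvectors of smallest nonzero eigenvalue (computed via the symmetric
  normalized Laplacian). Eigenvectors are sign-fixed (first entry of
  magnitude > 1e−9 positive) for reproducibility. Degenerate eigenvalues
  (e.g. complete graphs) admit any orthogonal basis of the eigenspace, so
  tests assert the eigen-residual, not a particular basis. Disconnected
  input is an error: the spectrum of a disconnected graph has a zero
  eigenvalue per component and the embedding should be done per component.
* **Matrix factorization** minimizes
  `sum_{(i,j)∈E} (1 − ⟨u_i,u_j⟩)² + reg·sum_i ‖u_i‖²` by seeded SGD over
  edges only (no negative sampling — the factorization objective it
  implements is defined on observed entries). Defaults: `d = 16`,
  `epochs = 100`, `lr = 0.025`, `reg = 1e−3`.
* **node2vec** generates second-order biased walks (weight `1/p` back to the
  predecessor, `1` to a neighbor of the predecessor, `1/q` otherwise; first
  step uniform) and trains skip-gram with negative sampling: 5-window, 5
  negatives drawn ∝ frequency^0.75, 5 epochs, learning rate decaying
  linearly 0.025 → 1e−4, subsampling off (walk corpora here are small).
  Defaults: walk length 40, 10 walks per node. DeepWalk is exposed as the
  `p = q = 1` case rather than a second implementation. The walk and
  training inner loops are in C++ but draw all randomness from R's RNG, so
  a seed fixes the output bitwise.

No encoder hyperparameters are dictated by the evaluation protocol; the
defaults above are this package's own and all are overridable.

**Composition.** The encoder–classifier route concatenates the two node
codes in canonical (`i < j`) order — concatenation is order-ambiguous for
undirected pairs, so fixing canonical order is required for `score(i,j) =
score(j,i)` — and trains a ridge-penalized logistic regression on all
observed edges (label 1) plus `neg_ratio · m` sampled non-edges (label 0,
`neg_ratio = 1` for balanced classes). The ridge (fixed `λ = 1e−3`,
intercept unpenalized, Newton/IRLS) keeps weights finite even when
embedding features separate the classes, and makes the fit deterministic.
The encoder–similarity route instead compares the two *node* codes with a
vector similarity (cosine, dot, L1/L2/Lp negated so larger is more similar,
Pearson with a zero-variance → 0 convention).

## Evaluation protocol

`make_test_split()` removes `round(ratio · m)` edges uniformly (10% is the
protocol default), keeps the full node set so IDs remain valid, optionally
injects false edges, and fixes everything by seed. Removal deliberately does
*not* require the observed network to stay connected — demanding
connectivity biases the benchmark toward dense graphs and is a known
limitation of earlier tooling; predictors here tolerate disconnected input.

**ROC.** The AUC is computed as the Mann–Whitney statistic (ties credit
0.5), which is exactly the area under the step curve through tie-grouped
points. The streaming mode sorts one class once and consumes the other in
bounded chunks, accumulating pair counts by binary search; it returns the
identical AUC to 1e−12 but no curve, since materializing the curve would
need both classes. Equal scores always enter the confusion matrix
atomically.

**Precision–recall.** Points are emitted per distinct threshold. The area
spans recall 0 to 1: the segment below the first attainable recall is
interpolated from the empty-prediction corner `(TP, FP) = (0, 0)`, which
holds the first point's precision constant (this is what the nonlinear
interpolation itself yields for that segment) — so a perfect ranking has
area exactly 1 under both rules, and no fictitious precision-1 anchor is
invented. The trapezoidal rule connects points linearly; the
Davis–Goadrich rule inserts the *achievable* operating points at each unit
TP step (FP interpolated linearly in TP) before integrating. While
precision is non-increasing along a segment the achievable curve is convex
and lies below the chord, which is why linear integration tends to
overestimate the area; a tie group that is positive-rich relative to the
cumulative precision makes precision rise and locally reverses this, so the
inequality is asserted (and guaranteed) in the non-increasing regime.

**General curves** map the swept confusion states through user-supplied
coordinate functions, starting from the empty-prediction state, and
integrate trapezoidally; `x = FP/N`, `y = TP/P` reproduces the ROC area to
machine precision, including on fully tied input (area 0.5). Non-monotone
`x` is an error, since the area is then undefined.

**Top-precision** is the fraction of removed edges among the top `l`
candidates (`l` defaults to the number removed). Both computations — scoring
the explicit candidate set, and taking the predictor's streamed top-`l` —
are provided and agree when the candidate sets coincide (negatives = all
ground-truth non-edges).

**Harness.** `run_experiment()` derives per-run and per-predictor seeds
from the master seed through a splitmix-style integer mix (kept below
2^31), so runs are mutually independent but the whole table is
byte-reproducible.

## The synthetic benchmark and what green tests mean

Tests and the acceptance script run on seeded Erdős–Rényi,
Barabási–Albert, and planted-partition generators. The recovery benchmark
is `gen_planted(200, 2, 0.3, 0.02)` with 10% hold-out: two equal blocks,
within-block density 0.3, cross-block 0.02 — a strong, recoverable
community signal at a size that keeps the full pipeline under a minute per
run. Blocks are assigned contiguously by ID, the usual planted-partition
convention. On this world the resource-allocation index reaches a mean ROC
AUC around 0.75–0.77 and the node2vec + logistic predictor around
0.7–0.8, both far above the 0.5 random baseline.

These graphs are exchangeable and unweighted, with Poisson-like (ER) or
power-law-ish (BA) degrees; they do not reproduce the degree correlations,
clustering spectra or noise processes of real interaction networks. A green
benchmark therefore establishes that the implementations are correct and
that the pipeline recovers planted structure — not that any particular
index is the best choice on a given real network.

## Numerical and degenerate-input conventions

* Unreachable distances are `Inf` with undefined (`NA`) hops.
* Zero-norm vectors have cosine similarity 0; zero-variance vectors have
  Pearson similarity 0; an empty neighbor union gives Jaccard 0.
* An empty network assembles validly; `m = 0` factorization returns its
  random initialization; degree-0 nodes yield length-1 walks.
* Score sheets are emitted in the canonical non-edge enumeration order;
  all ranking ties break lexicographically.
* Every stochastic component takes an explicit integer seed; derived seeds
  are mixed, never reused, and stay below 2^31.

## Known limitations

Directed networks, global probabilistic predictors (block models,
hierarchical random graphs, hyperbolic embeddings) and additional encoders
(LLE, LINE, LargeVis) are out of scope. The pure-R Dijkstra is quadratic
per source, adequate for the benchmark sizes here but not for
million-node graphs; the compiled kernels cover only the walk/skip-gram
hot path. PR-curve conventions differ across packages — comparisons of
absolute area values with other tools should check the anchoring convention
first.
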
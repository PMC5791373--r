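---
title: "Graph kernels for relation extraction: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph kernels for relation extraction: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relkern)
```

## The problem and the modelling assumptions

`relkern` classifies candidate entity pairs (chemical–disease, or
protein–protein) as related or unrelated from the dependency parses of the
sentences that mention them. Three assumptions underlie the whole design:

1. **Gold mentions.** Entity recognition and normalization are inputs, not
   outputs: every mention comes with character offsets and a concept id.
2. **Parses are inputs.** Dependency graphs arrive pre-computed (CoNLL-U,
   or bundled inside the unified PPI XML). Enhanced parses may contain
   undirected cycles, which is precisely why graph kernels are used instead
   of tree kernels.
3. **Path-concentrated evidence.** The shortest dependency path between two
   mentions is where relational evidence concentrates. Both kernels encode
   this through edge weights: 0.9 on the entity shortest path, 0.3
   elsewhere.

A pair whose mentions co-occur in some sentence is handled by the
*sentence-level* subsystem (one instance per co-mention sentence and
mention pair). A pair that never co-occurs is handled by the
*cross-sentence* subsystem: every sentence mentioning one concept is paired
with every sentence mentioning the other, the two graphs joined at their
roots by a directed `SentenceBoundary` edge. Document-level predictions are
the union of the two subsystems, with existential aggregation: a concept
pair is positive if any of its instances is.

## The APG kernel

Each labelled edge `l(a, b)` of the weighted dependency graph becomes an
*edge-node* vertex labelled `l` with two unlabeled edges `a -> n_l -> b`
carrying the original weight. A second, disconnected subgraph chains the
tokens in sentence order; its vertices carry the lemma plus a positional
label (`before`, `middle`, `after`, `entity1`, `entity2`) relative to the
focus pair. On the combined adjacency matrix `A`, the total connectivity

$$W = \sum_{i \ge 1} A^i = (I - A)^{-1} - I$$

sums, over every directed path, the product of its edge weights. With the
label allocation matrix `L`, `Gm = L W L^t` gives the total connectivity
between label pairs, and the kernel of two graphs is the Frobenius inner
product of their `Gm` matrices aligned on the union of their label sets
(absent labels contribute zero, so batch composition cannot change pairwise
values).

**Convergence guard.** The Neumann series converges only for spectral
radius $\rho(A) < 1$. Acyclic graphs are nilpotent and always safe; cyclic
enhanced graphs with large weights could in principle diverge. We compute
$\rho(A)$ first; if $\rho \ge 1 - 10^{-6}$ the default behaviour
(`convergence = "rescale"`) shrinks `A` by $0.99(1-10^{-6})/\rho$ with a
warning, while `convergence = "error"` aborts instead. With the default
weights (all $\le 0.9$) on sentence-scale graphs the guard essentially
never triggers.

**Linear-subgraph edge weight.** The recommended default edge weight is 0.3
for *all* edges, with 0.9 reserved for the entity shortest path, and we
apply that default to the linear chain as well (`w_linear = 0.3`,
configurable). This choice also has a practical face: with a 0.9 chain the
positional labels' connectivities decay so slowly that they come to
dominate the feature mass (on synthetic instances, over three quarters of
the squared norm), drowning the dependency subgraph in which the
path-weighted evidence lives.

**Position tags** are implemented as additional labels on the
linear-subgraph vertices — the allocation matrix explicitly supports
multi-label vertices — and are on by default; the test suite checks that
removing them changes kernel values and does not improve synthetic F1. For
a cross-sentence instance the linear chain concatenates both sentences'
tokens in document order (the per-sentence definition does not cover merged
instances; concatenation preserves the left-to-right reading).

## The ASM kernel

Over the union vocabulary of node labels, each graph maps every label to
the vertex bearing it, or to a disconnected dummy when absent. For every
ordered pair of distinct labels, the shortest path between the mapped
vertices (minimum hop count on the undirected topology) is summarized by a
sparse feature map:

- `distance`: product of all path-edge weights;
- `forward` / `backward`: the product restricted to edges traversed along /
  against their direction (empty product = 1);
- `edgelabel:l`: product of the weights of path edges bearing dependency
  label `l`.

The kernel sums, over ordered label pairs, the dot products of the two
graphs' feature maps; pairs involving a dummy or a disconnected vertex
contribute nothing. Because every instance thus has an explicit feature
vector, the package computes Gram matrices as sparse cross-products, which
is both fast and guarantees positive semi-definiteness.

Three points the kernel definition leaves open, and how we resolve them:

- **Duplicate labels.** Real sentences repeat lemmas, but the label-vertex
  mapping must be a bijection. Each label maps to its lowest-id bearer —
  deterministic and order-independent.
- **Ordered vs unordered pairs.** The direction features make the feature
  map order-sensitive, so the double sum runs over ordered pairs.
- **Label self-pairs.** A label paired with itself yields a degenerate
  all-ones feature map that adds the same constant to every kernel value;
  self-pairs are excluded by default (`include_diagonal = FALSE`).

**Tie-breaking.** Equal-length shortest paths are resolved by breadth-first
search with ascending-vertex-id neighbour expansion; the first discovery
wins. Determinism here is what makes the kernel exactly symmetric.

## Instance construction parameters

| parameter | default | meaning |
|---|---|---|
| `w_path` | 0.9 | weight of edges on the entity shortest path |
| `w_default` | 0.3 | weight of every other edge |
| `w_focus` | 0.9 | weight of the two focus edges (same emphasis as the path) |
| `w_linear` | 0.3 | linear-chain edge weight (APG) |
| `max_cross_distance` | Inf | cap on sentence-index distance for cross pairing |
| `C` | 1 | SVM regularization, deliberately untuned |

The focus vertices attach by directed edges (focus to entity) labelled
`focus`; label, direction and weight are not dictated by the kernel
definitions, so they are package choices: weight 0.9 accords the focus
attachment the same importance as the entity path itself. The
`SentenceBoundary` edge runs from the earlier sentence's root to the
later's with weight 0.3, and is re-weighted to 0.9 when it lies on the
entity shortest path — which, for a cross-sentence pair, it always does,
being the only edge joining the two components.

Multi-token mentions use as head the unique mention token whose syntactic
head lies outside the mention, falling back to the last token. Character
offsets are handled 0-based half-open throughout.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` produces CDR-style documents: 2–4 sentences of 6–10
tokens, random head-outward dependency trees (each token attaches to a
uniformly random earlier token), occasional extra enhanced-dependency edges
(probability 0.15 per sentence) that create undirected cycles, one chemical
and one disease mention per document, and a candidate pair that is positive
with probability 0.35 (candidate pairs in CDR-like corpora are
minority-positive). Mentions are blinded to the shared type lemmas
`chemical` / `disease`, the standard preprocessing for relation extraction.

The planted signal is lexical *and* structural, mirroring how
chemical-induced-disease statements are actually phrased. With probability
`1 - noise`, a positive pair's trigger lemma (`induce` or `cause`) is
planted on the dependency path between the mentions: in the same-sentence
case the trigger token becomes the direct governor of both mentions
(`nsubj`/`dobj`, as in "X induces Y"); in the cross-sentence case each
mention attaches directly under its sentence root and the trigger replaces
one root — the roots necessarily lie on the merged path. Negatives (and
the `noise` fraction of positives) are placed at random positions whose
shortest path has at least one intermediate vertex, and never contain a
trigger. A rule-based detector ("trigger on the entity path") therefore
solves the noise-free corpus exactly, upper-bounding the kernels; the test
suite verifies this, and verifies that both kernels learn the planted
signal far above a label-shuffled control at `noise = 0.1`.

What the generator does **not** emulate: real lexical diversity and
syntax (its vocabulary is 500 synthetic lemmas on random trees), multiple
mentions per concept, overlapping or discontinuous mentions, class ratios
of any particular benchmark, and relations expressed without any lexical
trigger. Passing the synthetic end-to-end test shows the pipeline is wired
correctly and the kernels detect path-borne evidence; it says nothing
about absolute performance on the external CDR or PPI corpora, which the
file readers support but which ship separately.

## Numerical choices and degenerate inputs

- Products of at most a few dozen weights in `(0,1]` are well inside double
  precision; no tolerances are needed in the feature maps. Oracle tests
  compare against literal formula evaluation at `1e-12` and against
  brute-force path enumeration at `1e-9`.
- `(I - A)^{-1}` uses a dense solve; after edge-node transformation a
  merged two-sentence instance stays well under a hundred vertices.
- Cosine normalization maps self-similarity to 1; an instance with a zero
  self-kernel (e.g. an empty graph) gets zero rows rather than `NaN`.
- Disconnected entity pairs are legal: `assign_edge_weights()` flags
  `no_path` and leaves weights at the default; the corresponding ASM
  feature map is the zero vector.
- `evaluate_pairs()` on empty gold and predicted sets reports 0 with an
  `undefined` flag rather than `NaN`.
- McNemar's test switches from the exact two-sided binomial to the
  continuity-corrected chi-square at `b + c = 25` discordant pairs.
- Gram matrices are symmetrized (`(K + K^t)/2`) to remove floating-point
  asymmetry before the SVM sees them.

## Problem sizes used in the test suite

Unit and property tests run on graphs of at most 8 vertices (where
exhaustive path enumeration is cheap) and corpora of 10–50 documents. The
end-to-end learnability check uses the 400-document planted-signal corpus
(200 train / 200 test, `noise = 0.1`, seed 7) — small enough to run in
about a minute, large enough that the binomial noise on F1 is a few
percent.

## Known limitations

- The ASM bijection keeps only the first bearer of a repeated lemma;
  evidence on later duplicates is invisible to the kernel. This is
  inherent to the label-bijection formulation, not to the implementation.
- Cross-sentence instance counts grow as the product of mention-bearing
  sentences; `max_cross_distance` exists to cap this on pathological
  documents.
- The SVM is intentionally untuned (`C = 1`); no class weighting is
  applied by default, though both are exposed as knobs.
- Kernel values are computed via explicit feature vectors. This is exact
  for both kernels (each is an inner product of finite sparse vectors) but
  means memory grows with the union feature space of a batch; batches of a
  few thousand instances are unproblematic.
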
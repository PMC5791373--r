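# relkern

Graph kernels for biomedical relation extraction in R.

Extracting relations such as chemical-induced disease (CID) or
protein-protein interaction (PPI) from the literature is usually cast as
supervised classification of candidate entity pairs. When the input is a
syntactic parse — a directed, edge-labelled dependency graph over a
sentence's tokens — kernel methods let an SVM compare two parses directly,
without hand-engineered feature vectors. `relkern` implements the two graph
kernels that can handle arbitrary dependency graphs (including the cyclic
ones produced by enhanced parses), plus everything needed to run them on
annotated corpora: instance construction for both within-sentence and
cross-sentence relations, Gram-matrix SVM classification, evaluation, and a
synthetic corpus generator so the whole pipeline is testable offline.

## The two kernels

Both kernels first re-weight the dependency graph: every edge gets the
default weight 0.3, and edges on the shortest path between the two entities
in focus get 0.9, concentrating attention where relational evidence lives.
Dedicated `Entity1`/`Entity2` focus vertices mark which of the sentence's
entity pairs an instance is about, and a relation whose mentions never share
a sentence is handled by joining the two sentence graphs with a
`SentenceBoundary` edge at their roots.

**All Path Graph (APG) kernel.** Edge labels are turned into intervening
vertices, yielding an unlabelled weighted digraph with adjacency matrix *A*.
The connectivity of a path is the product of its edge weights, and the total
connectivity between every vertex pair over *all* paths is the Neumann series

> W = Σᵢ Aⁱ = (I − A)⁻¹ − I.

With the label allocation matrix *L* (*L*[i,j] = 1 iff label *lᵢ* is on
vertex *vⱼ*), the label-pair connectivity is *Gᵐ = L W Lᵀ* and the kernel is
the Frobenius inner product K(G₁,G₂) = Σᵢⱼ G₁ᵐ[lᵢ,lⱼ]·G₂ᵐ[lᵢ,lⱼ]. A second,
disconnected subgraph encodes the sentence's word order with positional
labels (*before*/*middle*/*after*/*entity1*/*entity2*).

**Approximate Subgraph Matching (ASM) kernel.** Vertices are matched across
graphs by node label (missing labels get disconnected dummies); for every
ordered label pair the kernel compares the shortest paths between the
matched vertices through a feature map φ capturing structure, direction and
edge-label composition:

> φ_distance = Π W_e, φ_forward = Π_{f} W_f, φ_backward = Π_{b} W_b,
> φ_l = Π W_e^{I(e has label l)},

and K(G₁,G₂) = Σᵢⱼ φ(P¹)·φ(P²). The edge weighting makes this the
*edge-weighted* ASM variant: the entity shortest path is positively
discriminated against all other paths.

## Worked example

The sentence *"Seizures were caused by Alcohol and Fatigue"* has an enhanced
dependency graph whose undirected form contains a cycle; for the entity pair
(seizures, fatigue) the shortest path runs through "caused":

```r
library(relkern)
f <- fig1_fixture()
p <- shortest_path(f$graph, f$e1, f$e2)
p
#>   from to   label weight forward
#> 1    3  1   nsubj    0.9   FALSE
#> 2    3  7 nmod:by    0.9    TRUE
path_feature_map(p)
#>          distance           forward          backward edgelabel:nmod:by
#>              0.81              0.90              0.90              0.90
#>   edgelabel:nsubj
#>              0.90
```

The path has two 0.9-weighted edges, one traversed backward (`nsubj`,
against its direction) and one forward (`nmod:by`), so the distance feature
is 0.9² = 0.81 and the direction and edge-label features are each 0.9.

End to end, on a synthetic corpus with a planted trigger-on-path signal:

```r
cfg <- gen_config(n_documents = 60, noise = 0.1, seed = 7)
ins <- unlist(lapply(generate_corpus(cfg), build_instances), recursive = FALSE)
gold <- vapply(ins, `[[`, "", "label")
G <- gram(ins[1:40], "apg")           # precomputed normalized Gram matrix
m <- train_svm(G, gold[1:40])          # C-SVM, C = 1
pred <- predict_svm(m, cross_gram(ins[41:60], G))
evaluate_labels(gold[41:60], pred$labels)
#> P=1.000 R=1.000 F1=1.000 (tp=5 fp=0 fn=0)
```

`aggregate_document()` merges instance predictions into document-level
concept pairs (a pair is positive if any of its instances is),
`auc_score()` gives the rank-based AUC, and `mcnemar_test()` compares two
classifiers' accuracy on paired predictions.

A thin command-line front end over the same functions is installed at
`system.file("cli", "relkern", package = "relkern")` with subcommands
`generate`, `instances`, `gram`, `train`, `predict`, `eval` and `mcnemar`.

## Corpus formats

- **CoNLL-U** (`read_conllu()` / `write_conllu()`): parsed sentences; the
  enhanced-dependency DEPS column is used when present.
- **Unified PPI XML** (`read_ppi_xml()`): the dialect used to distribute
  AIMed, BioInfer, HPRD50, IEPA and LLL, with bundled tokenization and
  parses; candidate pairs become labelled sentence-level instances.
- **PubTator** (`read_pubtator()` / `read_cdr_corpus()`): title/abstract
  documents with entity mentions and document-level relations, paired with
  a CoNLL-U file of parses for CDR-style chemical-disease extraction.

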
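#' Label-vertex mapping for the ASM kernel
#'
#' The ASM kernel matches vertices across two graphs by node label: over the
#' union vocabulary of the two graphs' labels, each graph maps every label
#' either to the vertex bearing it or, when the label is absent, to a fresh
#' disconnected dummy vertex. Dummies never lie on a path, so label pairs
#' involving a dummy contribute nothing to the kernel. When one graph carries
#' the same label on several vertices, the label maps to its lowest-id bearer
#' (real sentences repeat lemmas; the mapping must be a bijection).
#'
#' @param g1,g2 [dep_graph()]s.
#' @return A list with `vocabulary` (sorted label union) and, per graph, a
#'   named integer vector `map` (label -> vertex id, `NA` for dummies).
#' @export
make_label_vertex_map <- function(g1, g2) {
  vocab <- sort(unique(c(g1$vertices$label, g2$vertices$label)))
  list(vocabulary = vocab,
       map1 = label_map(g1, vocab),
       map2 = label_map(g2, vocab))
}

label_map <- function(g, vocab = sort(unique(g$vertices$label))) {
  v <- g$vertices[order(g$vertices$id), , drop = FALSE]
  first <- v[!duplicated(v$label), , drop = FALSE]
  stats::setNames(first$id[match(vocab, first$label)], vocab)
}

#' Shortest path between two vertices, with traversal directions
#'
#' Minimum-hop path on the undirected topology, found by breadth-first
#' search with deterministic tie-breaking (ascending-vertex-id expansion).
#' Each edge of the returned path is annotated with its traversal direction:
#' forward when it is walked source -> target, backward otherwise.
#'
#' @param graph a [dep_graph()].
#' @param u,v vertex ids.
#' @return A data.frame of path edges (`from`, `to`, `label`, `weight`,
#'   `forward`) in path order; a zero-row frame for `u == v`; `NULL` when the
#'   vertices are disconnected.
#' @export
shortest_path <- function(graph, u, v) {
  res <- bfs_path(graph, u, v)
  if (is.null(res)) return(NULL)
  path <- res$path
  path$forward <- res$forward
  rownames(path) <- NULL
  path
}

#' Feature map of a shortest path
#'
#' Maps a direction-annotated path to the ASM kernel's sparse feature
#' vector. With `W_e` the weight of edge `e`:
#' * `distance`: `prod(W_e)` over all path edges (structural similarity);
#' * `forward` / `backward`: the product restricted to forward- /
#'   backward-traversed edges (empty product = 1);
#' * `edgelabel:<l>`: `prod(W_e ^ [e has label l])` for every dependency
#'   label `l` occurring on the path.
#'
#' An empty path (a vertex paired with itself) yields all-1
#' distance/forward/backward features and no edge-label features. A `NULL`
#' path (disconnected vertices) yields the zero vector, whose dot product
#' with anything is 0.
#'
#' @param path a path as returned by [shortest_path()], or `NULL`.
#' @return A named numeric vector (possibly empty).
#' @export
path_feature_map <- function(path) {
  if (is.null(path)) return(stats::setNames(numeric(0), character(0)))
  if (nrow(path) == 0L)
    return(c(distance = 1, forward = 1, backward = 1))
  w <- path$weight
  feats <- c(distance = prod(w),
             forward = prod(w[path$forward]),
             backward = prod(w[!path$forward]))
  lab <- vapply(split(w, path$label), prod, numeric(1))
  c(feats, stats::setNames(lab, paste0("edgelabel:", names(lab))))
}

SEP <- "\x1f"  # joins label-pair components in flattened feature names

# Explicit feature vector of one graph for the ASM kernel: the concatenation
# over ordered label pairs (l_i, l_j), i != j, of the path feature map from
# the vertex bearing l_i to the vertex bearing l_j. Names are
# l_i SEP l_j SEP feature. The kernel is the dot product of two such
# vectors over shared names, which makes Gram matrices PSD by construction.
asm_feature_vector <- function(g, include_diagonal = FALSE) {
  map <- label_map(g)
  labs <- names(map)
  adj <- adjacency_list(g)
  out <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    src <- map[[i]]
    tree <- bfs_tree(g, src, adj = adj)   # one BFS reaches every target
    feats <- list()
    for (j in seq_along(labs)) {
      if (i == j && !include_diagonal) next
      res <- bfs_extract(tree, src, map[[j]])
      if (is.null(res)) next
      path <- g$edges[res$eidx, , drop = FALSE]
      path$forward <- res$forward
      phi <- path_feature_map(path)
      if (length(phi))
        feats[[length(feats) + 1L]] <- stats::setNames(
          phi, paste(labs[i], labs[j], names(phi), sep = SEP))
    }
    out[[i]] <- unlist(feats)
  }
  vec <- unlist(out)
  if (is.null(vec)) stats::setNames(numeric(0), character(0)) else vec
}

#' Approximate Subgraph Matching kernel
#'
#' Edge-weighted ASM kernel score between two dependency graphs: the sum,
#' over ordered pairs of distinct node labels in the union vocabulary, of the
#' dot product of the two graphs' shortest-path feature maps (see
#' [path_feature_map()]) for the vertices mapped to that label pair. Label
#' pairs where either graph holds a dummy (missing label) or has no
#' connecting path contribute 0. Symmetric and non-negative.
#'
#' @param g1,g2 [dep_graph()]s.
#' @param include_diagonal also sum label self-pairs `(l, l)`; these have
#'   degenerate all-1 feature maps and add a constant, so they are excluded
#'   by default.
#' @return A non-negative number.
#' @export
asm_kernel <- function(g1, g2, include_diagonal = FALSE) {
  v1 <- asm_feature_vector(g1, include_diagonal)
  v2 <- asm_feature_vector(g2, include_diagonal)
  common <- intersect(names(v1), names(v2))
  if (!length(common)) return(0)
  sum(v1[common] * v2[common])
}

#' Cosine-normalized ASM kernel
#'
#' `K(g1,g2) / sqrt(K(g1,g1) K(g2,g2))`; 0 when either self-kernel is 0.
#' Equals 1 for a graph with itself.
#'
#' @inheritParams asm_kernel
#' @return A number in `[0, 1]`.
#' @export
asm_normalized <- function(g1, g2, include_diagonal = FALSE) {
  k11 <- asm_kernel(g1, g1, include_diagonal)
  k22 <- asm_kernel(g2, g2, include_diagonal)
  if (k11 <= 0 || k22 <= 0) return(0)
  asm_kernel(g1, g2, include_diagonal) / sqrt(k11 * k22)
}
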
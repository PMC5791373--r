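# Brute-force oracles kept deliberately independent of the package's own
# algorithms: exhaustive simple-path enumeration for shortest paths, literal
# path-product enumeration and truncated Neumann series for connectivity.

# Minimum hop count between u and v by exhaustive enumeration of all simple
# paths on the undirected topology. Inf when disconnected.
oracle_min_hops <- function(g, u, v) {
  if (u == v) return(0L)
  nbrs <- function(x) unique(c(g$edges$to[g$edges$from == x],
                               g$edges$from[g$edges$to == x]))
  best <- Inf
  walk <- function(cur, visited, depth) {
    if (depth >= best) return(invisible())
    for (nb in nbrs(cur)) {
      if (nb == v) { best <<- min(best, depth + 1L); next }
      if (!(nb %in% visited)) walk(nb, c(visited, nb), depth + 1L)
    }
  }
  walk(u, u, 0L)
  best
}

# Sum of edge-weight products over all directed paths u -> v in an acyclic
# weighted adjacency matrix, by explicit enumeration.
oracle_dag_connectivity <- function(A) {
  n <- nrow(A)
  W <- matrix(0, n, n)
  paths_from <- function(u, v) {
    total <- 0
    for (k in seq_len(n)) {
      if (A[u, k] > 0) {
        if (k == v) total <- total + A[u, k]
        total <- total + A[u, k] * paths_from(k, v)
      }
    }
    total
  }
  for (u in seq_len(n)) for (v in seq_len(n)) W[u, v] <- paths_from(u, v)
  W
}

# Truncated Neumann series sum_{i=1..k} A^i.
oracle_series_connectivity <- function(A, k = 50) {
  W <- matrix(0, nrow(A), ncol(A))
  P <- diag(nrow(A))
  for (i in seq_len(k)) {
    P <- P %*% A
    W <- W + P
  }
  W
}

# Random weighted digraph adjacency matrix on n vertices. Acyclic graphs
# only use upper-triangular edges; cyclic graphs allow any direction and
# are rescaled to spectral radius 0.5 so the truncated series converges
# well below the comparison tolerance.
random_adjacency <- function(n, cyclic = FALSE) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (!cyclic && i > j) next
    if (stats::runif(1) < 0.35) A[i, j] <- stats::runif(1, 0.1, 0.9)
  }
  if (cyclic) {
    rho <- max(Mod(eigen(A, only.values = TRUE)$values))
    if (rho > 0) A <- A * (0.5 / rho)
  }
  A
}

# Random labelled dep_graph with distinct single-character labels.
random_dep_graph <- function(n, p_edge = 0.35) {
  labels <- paste0("v", seq_len(n))
  edges <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && stats::runif(1) < p_edge)
      edges <- rbind(edges, data.frame(
        from = i, to = j, label = sample(c("nsubj", "dobj", "amod"), 1),
        weight = stats::runif(1, 0.1, 0.9), stringsAsFactors = FALSE))
  }
  if (!is.null(edges))
    edges <- edges[!duplicated(edges[, c("from", "to", "label")]), ]
  dep_graph(data.frame(id = seq_len(n), label = labels, kind = "token",
                       stringsAsFactors = FALSE),
            edges, roots = 1L)
}

# Tiny two-sentence corpus fixtures used across tests.
toy_sentence <- function(lemmas, heads, labels) {
  list(tokens = data.frame(id = seq_along(lemmas), form = lemmas,
                           lemma = lemmas, upos = "X", misc = "_",
                           stringsAsFactors = FALSE),
       deps = data.frame(head = heads, dep = seq_along(lemmas),
                         label = labels, stringsAsFactors = FALSE),
       meta = character(), enhanced = FALSE)
}

small_corpus_instances <- function(n_documents = 12, noise = 0, seed = 42,
                                   ...) {
  cfg <- gen_config(n_documents = n_documents, noise = noise, seed = seed, ...)
  unlist(lapply(generate_corpus(cfg), build_instances), recursive = FALSE)
}
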
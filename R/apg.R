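#' Transform a dependency graph for the All Path Graph kernel
#'
#' The APG kernel operates on edge-weighted graphs without edge labels.
#' Every labelled edge `l(a, b)` with weight `w` becomes a fresh edge-node
#' vertex labelled `l` plus two unlabeled directed edges `a -> n_l` and
#' `n_l -> b`, both of weight `w`. Token and focus vertices keep their
#' labels.
#'
#' @param graph a weighted [dep_graph()].
#' @return An `apg_graph` fragment: list with `labels` (list of character
#'   label sets, one per vertex), `edges` (data.frame `from`, `to`, `weight`
#'   of vertex indices) and `kind` per vertex.
#' @export
transform_dependency_subgraph <- function(graph) {
  v <- graph$vertices
  nv <- nrow(v); ne <- nrow(graph$edges)
  labels <- as.list(v$label)
  kind <- v$kind
  idx <- match(graph$edges$from, v$id)
  jdx <- match(graph$edges$to, v$id)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(ne)) {
    node <- nv + k
    labels[[node]] <- graph$edges$label[k]
    kind[node] <- "edge-node"
    from <- c(from, idx[k], node)
    to <- c(to, node, jdx[k])
    w <- c(w, graph$edges$weight[k], graph$edges$weight[k])
  }
  structure(list(labels = labels,
                 edges = data.frame(from = from, to = to, weight = w),
                 kind = kind),
            class = "apg_graph")
}

#' Linear-order subgraph with positional labels
#'
#' The second APG subgraph encodes the sentence's word order: one vertex per
#' token, chained left to right by `n - 1` directed edges of weight
#' `w_linear`. Besides its lemma, each vertex carries a positional label
#' relative to the entity pair in focus: `entity1`, `entity2`, `before`,
#' `middle` or `after`. Leaving the positional labels out measurably hurts
#' relation extraction, so they are on by default.
#'
#' @param tokens data.frame with a `lemma` column, in sentence order (for a
#'   cross-sentence instance, both sentences' tokens in document order).
#' @param e1_pos,e2_pos row indices of the two entity head tokens.
#' @param w_linear edge weight of the linear chain (default 0.3, the
#'   recommended default weight for all edges; configurable).
#' @param position_tags add the positional labels (default `TRUE`).
#' @return An `apg_graph` fragment (same shape as
#'   [transform_dependency_subgraph()]).
#' @export
build_linear_subgraph <- function(tokens, e1_pos, e2_pos, w_linear = 0.3,
                                  position_tags = TRUE) {
  n <- nrow(tokens)
  if (n < 1L) stop("empty token sequence")
  if (e1_pos == e2_pos) stop("entity positions must be distinct")
  lo <- min(e1_pos, e2_pos); hi <- max(e1_pos, e2_pos)
  labels <- lapply(seq_len(n), function(i) {
    tag <- if (i == e1_pos) "entity1" else if (i == e2_pos) "entity2"
           else if (i < lo) "before" else if (i > hi) "after" else "middle"
    if (position_tags) c(tolower(tokens$lemma[i]), tag) else tolower(tokens$lemma[i])
  })
  edges <- if (n > 1L)
    data.frame(from = seq_len(n - 1L), to = seq(2L, n), weight = w_linear)
  else data.frame(from = integer(), to = integer(), weight = numeric())
  structure(list(labels = labels, edges = edges, kind = rep("token", n)),
            class = "apg_graph")
}

# Disjoint union of apg_graph fragments (no connecting edges).
combine_apg <- function(...) {
  frags <- list(...)
  labels <- list(); kind <- character(); edges <- NULL; offset <- 0L
  for (f in frags) {
    labels <- c(labels, f$labels)
    kind <- c(kind, f$kind)
    e <- f$edges
    if (nrow(e)) { e$from <- e$from + offset; e$to <- e$to + offset }
    edges <- rbind(edges, e)
    offset <- offset + length(f$labels)
  }
  structure(list(labels = labels, edges = edges, kind = kind),
            class = "apg_graph")
}

apg_adjacency <- function(g) {
  n <- length(g$labels)
  A <- matrix(0, n, n)
  e <- g$edges
  if (!is.null(e) && nrow(e)) A[cbind(e$from, e$to)] <- e$weight
  A
}

#' Total connectivity matrix of a weighted digraph
#'
#' The connectivity of a directed path is the product of its edge weights;
#' `W[u, v]` sums the connectivity of every directed path from `u` to `v`,
#' i.e. the Neumann series `A + A^2 + ...`, computed in closed form as
#' `(I - A)^-1 - I`. The series converges only when the spectral radius of
#' `A` is below 1; with a cyclic graph and large weights it can diverge, so
#' the radius is checked first and, under `convergence = "rescale"`, `A` is
#' shrunk just inside the unit radius with a warning (with `"error"` an
#' error is raised instead).
#'
#' @param A square weighted adjacency matrix (entries in `[0, 1)` expected).
#' @param convergence `"rescale"` or `"error"`.
#' @return The matrix `W`, with a zero diagonal contribution from `W - I`.
#' @export
connectivity <- function(A, convergence = c("rescale", "error")) {
  convergence <- match.arg(convergence)
  n <- nrow(A)
  if (n == 0L) return(A)
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho >= 1 - 1e-6) {
    if (convergence == "error")
      stop(sprintf("connectivity series diverges: spectral radius %.4f", rho))
    warning(sprintf("spectral radius %.4f >= 1; rescaling edge weights", rho))
    A <- A * (0.99 * (1 - 1e-6) / rho)
  }
  solve(diag(n) - A) - diag(n)
}

#' Label-pair connectivity of an APG graph
#'
#' Builds the label allocation matrix `L` (`L[i, j] = 1` iff label `l_i` is
#' present on vertex `v_j`; a vertex may carry several labels) over the
#' graph's own label set, sorted canonically, and returns
#' `Gm = L W L^T`: the total connectivity between any vertex bearing one
#' label and any vertex bearing the other.
#'
#' @param g an `apg_graph` (combined dependency + linear fragments).
#' @inheritParams connectivity
#' @return A list with `A`, `W`, `L` and `Gm` (labels x labels, dimnames set).
#' @export
label_connectivity <- function(g, convergence = "rescale") {
  A <- apg_adjacency(g)
  W <- connectivity(A, convergence)
  labs <- sort(unique(unlist(g$labels)))
  L <- matrix(0, length(labs), length(g$labels),
              dimnames = list(labs, NULL))
  for (j in seq_along(g$labels)) L[g$labels[[j]], j] <- 1
  Gm <- L %*% W %*% t(L)
  dimnames(Gm) <- list(labs, labs)
  list(A = A, W = W, L = L, Gm = Gm)
}

# Flattened sparse feature vector of Gm: names "li SEP lj", nonzero entries
# only. The APG kernel of two graphs is the dot product over shared names,
# equal to the Frobenius inner product of the label-aligned Gm matrices.
apg_feature_vector <- function(gm) {
  nz <- which(gm != 0, arr.ind = TRUE)
  if (!nrow(nz)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(gm[nz],
                  paste(rownames(gm)[nz[, 1]], colnames(gm)[nz[, 2]], sep = SEP))
}

#' Assemble the APG graph of a relation instance
#'
#' Combines the edge-label-to-vertex transformation of the instance's
#' (weighted, focus-marked) dependency graph with the linear word-order
#' subgraph into the final disconnected two-part graph the APG kernel
#' operates on.
#'
#' @param instance a `relation_instance` from [build_instances()].
#' @param w_linear linear-chain edge weight.
#' @param position_tags include positional labels in the linear subgraph.
#' @return An `apg_graph`.
#' @export
as_apg_graph <- function(instance, w_linear = 0.3, position_tags = TRUE) {
  dep <- transform_dependency_subgraph(instance$graph)
  lin <- build_linear_subgraph(instance$linear_tokens,
                               instance$linear_e1, instance$linear_e2,
                               w_linear = w_linear,
                               position_tags = position_tags)
  combine_apg(dep, lin)
}

#' All Path Graph kernel
#'
#' APG kernel score between two relation instances: the label spaces of the
#' two `Gm` matrices are aligned on the union of their labels (absent labels
#' contribute zero rows/columns) and the score is the Frobenius inner
#' product `sum_ij Gm1[l_i, l_j] * Gm2[l_i, l_j]`. Symmetric and, with all
#' weights positive, non-negative.
#'
#' @param i1,i2 `relation_instance`s (or `apg_graph`s).
#' @param w_linear,position_tags see [as_apg_graph()].
#' @param convergence see [connectivity()].
#' @return A non-negative number.
#' @export
apg_kernel <- function(i1, i2, w_linear = 0.3, position_tags = TRUE,
                       convergence = "rescale") {
  v1 <- apg_instance_features(i1, w_linear, position_tags, convergence)
  v2 <- apg_instance_features(i2, w_linear, position_tags, convergence)
  common <- intersect(names(v1), names(v2))
  if (!length(common)) return(0)
  sum(v1[common] * v2[common])
}

apg_instance_features <- function(x, w_linear = 0.3, position_tags = TRUE,
                                  convergence = "rescale") {
  g <- if (inherits(x, "apg_graph")) x
       else as_apg_graph(x, w_linear, position_tags)
  apg_feature_vector(label_connectivity(g, convergence)$Gm)
}

#' Cosine-normalized APG kernel
#'
#' `K(i1,i2) / sqrt(K(i1,i1) K(i2,i2))`; 0 when either self-kernel is 0.
#'
#' @inheritParams apg_kernel
#' @return A number in `[0, 1]`.
#' @export
apg_normalized <- function(i1, i2, w_linear = 0.3, position_tags = TRUE,
                           convergence = "rescale") {
  v1 <- apg_instance_features(i1, w_linear, position_tags, convergence)
  v2 <- apg_instance_features(i2, w_linear, position_tags, convergence)
  k11 <- sum(v1 * v1); k22 <- sum(v2 * v2)
  if (k11 <= 0 || k22 <= 0) return(0)
  common <- intersect(names(v1), names(v2))
  k12 <- if (length(common)) sum(v1[common] * v2[common]) else 0
  k12 / sqrt(k11 * k22)
}
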
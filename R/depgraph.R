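#' Dependency parse graphs
#'
#' A `dep_graph` holds one (possibly merged) dependency parse: one vertex per
#' token plus any special vertices (entity-focus, APG edge-nodes), and one
#' directed labelled edge per grammatical relation. Edge weights live in
#' `(0, 1]`; the default weight is 0.3 and edges on the shortest path between
#' the two entities in focus are up-weighted to 0.9 (see
#' [assign_edge_weights()]).
#'
#' @param vertices data.frame with columns `id` (unique integer), `label`
#'   (non-empty character; the token lemma for token vertices) and `kind`
#'   (one of `"token"`, `"edge-node"`, `"focus"`, `"dummy"`).
#' @param edges data.frame with columns `from`, `to` (vertex ids), `label`
#'   (character) and `weight` (numeric in `(0, 1]`).
#' @param roots integer vector of sentence-head vertex ids, one per merged
#'   sentence.
#' @param no_path logical flag set by [assign_edge_weights()] when the two
#'   entities are disconnected.
#'
#' @return An object of class `dep_graph`.
#' @export
dep_graph <- function(vertices, edges = NULL, roots = integer(), no_path = FALSE) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = integer(), to = integer(),
                        label = character(), weight = numeric())
  }
  vertices <- as.data.frame(vertices)
  edges <- as.data.frame(edges)
  rownames(vertices) <- NULL
  rownames(edges) <- NULL
  if (!"kind" %in% names(vertices)) vertices$kind <- "token"
  if (!"weight" %in% names(edges)) edges$weight <- 0.3
  g <- structure(list(vertices = vertices, edges = edges,
                      roots = as.integer(roots), no_path = isTRUE(no_path)),
                 class = "dep_graph")
  validate_dep_graph(g)
  g
}

validate_dep_graph <- function(g) {
  v <- g$vertices; e <- g$edges
  stopifnot(is.data.frame(v), is.data.frame(e))
  if (anyDuplicated(v$id)) stop("dep_graph: duplicate vertex ids")
  if (any(!nzchar(v$label))) stop("dep_graph: empty vertex label")
  if (nrow(e)) {
    if (!all(e$from %in% v$id) || !all(e$to %in% v$id))
      stop("dep_graph: edge endpoint not among vertices")
    if (any(e$weight <= 0 | e$weight > 1))
      stop("dep_graph: edge weights must lie in (0, 1]")
    if (anyDuplicated(e[, c("from", "to", "label")]))
      stop("dep_graph: duplicate (source, target, label) edge")
  }
  invisible(g)
}

#' @export
print.dep_graph <- function(x, ...) {
  cat(sprintf("<dep_graph: %d vertices, %d edges, %d root(s)%s>\n",
              nrow(x$vertices), nrow(x$edges), length(x$roots),
              if (x$no_path) ", no entity path" else ""))
  invisible(x)
}

n_vertices <- function(g) nrow(g$vertices)
n_edges <- function(g) nrow(g$edges)

vertex_label <- function(g, id) g$vertices$label[match(id, g$vertices$id)]

#' Build the dependency graph of a parsed sentence
#'
#' One vertex per token (labelled with its lowercased lemma), one directed
#' edge per dependency relation, direction governor -> dependent. All edge
#' weights are initialized to `w_default`.
#'
#' @param sentence a sentence record as returned by [read_conllu()]: a list
#'   with a `tokens` data.frame (`id`, `form`, `lemma`, ...) and a `deps`
#'   data.frame (`head`, `dep`, `label`).
#' @param w_default initial weight for every edge (default 0.3).
#' @return A [dep_graph()] whose roots are the tokens governed by the
#'   artificial root (head 0).
#' @export
build_dep_graph <- function(sentence, w_default = 0.3) {
  tok <- sentence$tokens
  deps <- sentence$deps
  vertices <- data.frame(id = tok$id, label = tolower(tok$lemma),
                         kind = "token", stringsAsFactors = FALSE)
  roots <- if (nrow(deps)) deps$dep[deps$head == 0L] else tok$id[1L]
  if (!length(roots) && nrow(tok)) roots <- tok$id[1L]
  real <- deps[deps$head != 0L, , drop = FALSE]
  edges <- data.frame(from = real$head, to = real$dep, label = real$label,
                      weight = rep(w_default, nrow(real)),
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  dep_graph(vertices, edges, roots = roots)
}

# Undirected adjacency list with deterministic ordering: for each vertex, the
# incident edges sorted by (neighbour id, edge index). Returned as a list of
# data.frames with columns nbr, edge (row index into g$edges), forward.
adjacency_list <- function(g) {
  ids <- g$vertices$id
  adj <- stats::setNames(vector("list", length(ids)), as.character(ids))
  e <- g$edges
  if (nrow(e)) {
    inc <- rbind(
      data.frame(v = e$from, nbr = e$to, edge = seq_len(nrow(e)), forward = TRUE),
      data.frame(v = e$to, nbr = e$from, edge = seq_len(nrow(e)), forward = FALSE)
    )
    inc <- inc[order(inc$v, inc$nbr, inc$edge), ]
    for (grp in split(inc, factor(inc$v, levels = ids))) {
      if (nrow(grp)) adj[[as.character(grp$v[1L])]] <- grp
    }
  }
  adj
}

# Full BFS tree from one source under the same deterministic expansion
# order as bfs_path. Returns an environment keyed by vertex id with
# list(edge, prev, forward) records (edge = NA at the source).
bfs_tree <- function(g, from, adj = adjacency_list(g)) {
  parent <- new.env(parent = emptyenv())
  assign(as.character(from), list(edge = NA, prev = NA, forward = NA), envir = parent)
  queue <- from
  head <- 1L
  while (head <= length(queue)) {
    u <- queue[[head]]; head <- head + 1L
    grp <- adj[[as.character(u)]]
    if (is.null(grp)) next
    for (k in seq_len(nrow(grp))) {
      v <- grp$nbr[k]
      key <- as.character(v)
      if (!exists(key, envir = parent, inherits = FALSE)) {
        assign(key, list(edge = grp$edge[k], prev = u, forward = grp$forward[k]),
               envir = parent)
        queue <- c(queue, v)
      }
    }
  }
  parent
}

# Reconstruct the path from the BFS source to `to` out of a bfs_tree().
# Returns list(eidx, forward) or NULL when unreached.
bfs_extract <- function(parent, from, to) {
  key <- as.character(to)
  if (!exists(key, envir = parent, inherits = FALSE)) return(NULL)
  eidx <- integer(); fwd <- logical(); cur <- to
  while (cur != from) {
    rec <- get(as.character(cur), envir = parent)
    eidx <- c(rec$edge, eidx); fwd <- c(rec$forward, fwd)
    cur <- rec$prev
  }
  list(eidx = eidx, forward = fwd)
}

# Breadth-first shortest path on the undirected topology, hop-count metric.
# Deterministic tie-break: vertices are expanded in queue order and a
# vertex's neighbours in ascending (neighbour id, edge index) order; the
# first discovery wins. Returns list(path = data.frame(edge rows + forward
# flag), vertices = id sequence) or NULL when unreachable.
bfs_path <- function(g, from, to, adj = adjacency_list(g)) {
  ids <- g$vertices$id
  if (!(from %in% ids) || !(to %in% ids))
    stop("unknown vertex id: ", if (!(from %in% ids)) from else to)
  if (from == to)
    return(list(path = g$edges[0, , drop = FALSE], vertices = from,
                forward = logical(0)))
  parent <- new.env(parent = emptyenv())
  assign(as.character(from), list(edge = NA, prev = NA, forward = NA), envir = parent)
  queue <- from
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    grp <- adj[[as.character(u)]]
    if (is.null(grp)) next
    for (k in seq_len(nrow(grp))) {
      v <- grp$nbr[k]
      key <- as.character(v)
      if (!exists(key, envir = parent, inherits = FALSE)) {
        assign(key, list(edge = grp$edge[k], prev = u, forward = grp$forward[k]),
               envir = parent)
        if (v == to) {
          # reconstruct
          eidx <- integer(); fwd <- logical(); verts <- v
          cur <- v
          while (cur != from) {
            rec <- get(as.character(cur), envir = parent)
            eidx <- c(rec$edge, eidx); fwd <- c(rec$forward, fwd)
            cur <- rec$prev; verts <- c(cur, verts)
          }
          return(list(path = g$edges[eidx, , drop = FALSE],
                      vertices = verts, forward = fwd, eidx = eidx))
        }
        queue <- c(queue, v)
      }
    }
  }
  NULL
}

#' Weight edges on the shortest dependency path between two entities
#'
#' Edges on one minimum-hop undirected path between the two entity vertices
#' receive `w_path` (0.9); every other edge receives `w_default` (0.3). The
#' up-weighting accords greater importance to the shortest dependency path,
#' which is where the relational evidence between the entities concentrates.
#' Ties between equal-length paths are broken deterministically by
#' breadth-first search with ascending-vertex-id expansion.
#'
#' @param graph a [dep_graph()].
#' @param e1,e2 entity vertex ids.
#' @param w_path weight for edges on the entity shortest path.
#' @param w_default weight for all remaining edges.
#' @return The reweighted graph. When `e1` and `e2` are disconnected all
#'   edges keep `w_default` and the `no_path` flag is set. Idempotent for a
#'   fixed pair; topology is never changed.
#' @export
assign_edge_weights <- function(graph, e1, e2, w_path = 0.9, w_default = 0.3) {
  ids <- graph$vertices$id
  if (!(e1 %in% ids)) stop("unknown vertex id: ", e1)
  if (!(e2 %in% ids)) stop("unknown vertex id: ", e2)
  graph$edges$weight <- rep(w_default, n_edges(graph))
  graph$no_path <- FALSE
  if (e1 == e2) return(graph)
  res <- bfs_path(graph, e1, e2)
  if (is.null(res)) {
    graph$no_path <- TRUE
    return(graph)
  }
  graph$edges$weight[res$eidx] <- w_path
  graph
}

#' Attach Entity1/Entity2 focus vertices
#'
#' A sentence may mention several entity pairs; the focus vertices mark which
#' pair an instance is about. Two fresh vertices labelled `"Entity1"` and
#' `"Entity2"` are added, each connected to its entity vertex by a directed
#' edge labelled `"focus"` with weight `w_focus`.
#'
#' @param graph a [dep_graph()] without existing focus vertices.
#' @param e1,e2 distinct entity vertex ids.
#' @param w_focus weight of the two focus edges (default 0.9, matching the
#'   entity-path weight).
#' @return The augmented graph (two more vertices and edges).
#' @export
attach_focus_vertices <- function(graph, e1, e2, w_focus = 0.9) {
  ids <- graph$vertices$id
  if (!(e1 %in% ids)) stop("unknown vertex id: ", e1)
  if (!(e2 %in% ids)) stop("unknown vertex id: ", e2)
  if (e1 == e2) stop("focus entities must be distinct")
  if (any(graph$vertices$kind == "focus"))
    stop("focus vertices already present")
  f1 <- max(ids) + 1L; f2 <- max(ids) + 2L
  graph$vertices <- rbind(graph$vertices,
                          data.frame(id = c(f1, f2), label = c("Entity1", "Entity2"),
                                     kind = "focus", stringsAsFactors = FALSE))
  graph$edges <- rbind(graph$edges,
                       data.frame(from = c(f1, f2), to = c(e1, e2),
                                  label = "focus", weight = w_focus,
                                  stringsAsFactors = FALSE))
  rownames(graph$edges) <- NULL
  validate_dep_graph(graph)
  graph
}

#' Merge two sentence graphs for a cross-sentence relation
#'
#' Relations whose entity mentions never co-occur in one sentence are handled
#' by joining the two sentences' graphs into one: the root of the earlier
#' sentence is connected to the root of the later sentence by a directed edge
#' with the reserved label `"SentenceBoundary"` and weight `w_boundary`.
#' Vertex ids of `g2` are shifted to avoid collision (returned as the
#' `offset` attribute).
#'
#' @param g1,g2 single-sentence [dep_graph()]s, `g1` preceding `g2` in
#'   document order.
#' @param w_boundary weight of the boundary edge (default 0.3; it is
#'   re-weighted to 0.9 by [assign_edge_weights()] when it lies on the entity
#'   shortest path, as it always does for a cross-sentence pair).
#' @return A merged graph with `|V1|+|V2|` vertices and `|E1|+|E2|+1` edges
#'   and two roots.
#' @export
merge_cross_sentence <- function(g1, g2, w_boundary = 0.3) {
  if (!length(g1$roots) || !length(g2$roots))
    stop("merge_cross_sentence: both graphs must have a root")
  offset <- max(g1$vertices$id)
  v2 <- g2$vertices; v2$id <- v2$id + offset
  e2 <- g2$edges
  if (nrow(e2)) { e2$from <- e2$from + offset; e2$to <- e2$to + offset }
  vertices <- rbind(g1$vertices, v2)
  boundary <- data.frame(from = g1$roots[1L], to = g2$roots[1L] + offset,
                         label = "SentenceBoundary", weight = w_boundary,
                         stringsAsFactors = FALSE)
  edges <- rbind(g1$edges, e2, boundary)
  rownames(edges) <- NULL
  g <- dep_graph(vertices, edges,
                 roots = c(g1$roots, g2$roots + offset))
  attr(g, "offset") <- offset
  g
}
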
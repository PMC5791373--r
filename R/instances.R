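#' Relation instances
#'
#' A `relation_instance` bundles everything the kernels need for one
#' candidate entity pair: the (weighted, focus-marked) dependency graph, the
#' focus vertex ids, the token sequence for the linear subgraph, the gold
#' label and provenance.
#'
#' @name relation_instance
NULL

new_relation_instance <- function(graph, focus, label, level, doc_id,
                                  sentences, concepts, linear_tokens,
                                  linear_e1, linear_e2) {
  structure(list(graph = graph, focus = focus, label = label, level = level,
                 doc_id = doc_id, sentences = sentences, concepts = concepts,
                 linear_tokens = linear_tokens,
                 linear_e1 = linear_e1, linear_e2 = linear_e2),
            class = "relation_instance")
}

#' @export
print.relation_instance <- function(x, ...) {
  cat(sprintf("<relation_instance %s (%s,%s) %s %s>\n", x$doc_id,
              x$concepts[1], x$concepts[2], x$level, x$label))
  invisible(x)
}

#' Build classification instances for a document
#'
#' Implements the two-subsystem construction. For every candidate concept
#' pair `(C, D)`:
#' * if at least one sentence mentions both concepts, each such sentence
#'   contributes sentence-level instances (one per mention pair in it);
#' * otherwise every sentence mentioning `C` is paired with every sentence
#'   mentioning `D`; the two sentence graphs are merged at their roots with
#'   a `"SentenceBoundary"` edge (cross-level instances).
#'
#' Each instance's graph then gets its entity shortest path re-weighted to
#' 0.9 ([assign_edge_weights()]) and Entity1/Entity2 focus vertices attached
#' ([attach_focus_vertices()]). The gold label is positive iff `(C, D)` is
#' among the document's gold relations.
#'
#' For CDR-style documents the candidate universe is every Chemical concept
#' crossed with every Disease concept that has at least one mention. For
#' PPI-style documents (a `pairs` table is present) the annotated candidate
#' pairs are used directly.
#'
#' @param doc a `document`.
#' @param w_path,w_default entity-path and default edge weights.
#' @param max_cross_distance maximum sentence-index distance for cross-level
#'   pairing (default `Inf`, i.e. unlimited).
#' @return A list of `relation_instance` objects.
#' @export
build_instances <- function(doc, w_path = 0.9, w_default = 0.3,
                            max_cross_distance = Inf) {
  graphs <- lapply(doc$sentences, build_dep_graph, w_default = w_default)
  if (!is.null(doc$pairs) && nrow(doc$pairs))
    return(ppi_instances(doc, graphs, w_path, w_default))
  ent <- doc$entities
  chems <- unique(ent$concept[ent$type == "Chemical"])
  dis <- unique(ent$concept[ent$type != "Chemical"])
  out <- list()
  for (C in chems) for (D in dis) {
    mC <- ent[ent$concept == C, , drop = FALSE]
    mD <- ent[ent$concept == D, , drop = FALSE]
    if (!nrow(mC) || !nrow(mD)) {
      warning(sprintf("concept pair (%s,%s) skipped: missing mention", C, D))
      next
    }
    gold <- any(doc$relations$c1 == C & doc$relations$c2 == D)
    label <- if (gold) "positive" else "negative"
    shared <- intersect(mC$sentence, mD$sentence)
    if (length(shared)) {
      for (s in shared) {
        for (hc in mC$head_token[mC$sentence == s])
          for (hd in mD$head_token[mD$sentence == s]) {
            if (hc == hd) next
            out[[length(out) + 1L]] <- sentence_instance(
              doc, graphs, s, hc, hd, C, D, label, w_path, w_default)
          }
      }
    } else {
      for (s1 in unique(mC$sentence)) for (s2 in unique(mD$sentence)) {
        if (s1 == s2 || abs(s1 - s2) > max_cross_distance) next
        hc <- mC$head_token[mC$sentence == s1][1L]
        hd <- mD$head_token[mD$sentence == s2][1L]
        out[[length(out) + 1L]] <- cross_instance(
          doc, graphs, s1, s2, hc, hd, C, D, label, w_path, w_default)
      }
    }
  }
  out
}

sentence_instance <- function(doc, graphs, s, e1, e2, C, D, label,
                              w_path, w_default) {
  g <- graphs[[s]]
  g <- assign_edge_weights(g, e1, e2, w_path, w_default)
  g <- attach_focus_vertices(g, e1, e2, w_focus = w_path)
  tok <- doc$sentences[[s]]$tokens
  new_relation_instance(g, focus = c(e1, e2), label = label,
                        level = "sentence", doc_id = doc$id, sentences = s,
                        concepts = c(C, D), linear_tokens = tok,
                        linear_e1 = match(e1, tok$id),
                        linear_e2 = match(e2, tok$id))
}

cross_instance <- function(doc, graphs, s1, s2, e1, e2, C, D, label,
                           w_path, w_default) {
  # merge in document order, whichever sentence holds which entity
  a <- min(s1, s2); b <- max(s1, s2)
  merged <- merge_cross_sentence(graphs[[a]], graphs[[b]], w_boundary = w_default)
  offset <- attr(merged, "offset")
  v1 <- if (s1 == a) e1 else e1 + offset
  v2 <- if (s2 == a) e2 else e2 + offset
  merged <- assign_edge_weights(merged, v1, v2, w_path, w_default)
  merged <- attach_focus_vertices(merged, v1, v2, w_focus = w_path)
  tokA <- doc$sentences[[a]]$tokens
  tokB <- doc$sentences[[b]]$tokens
  tok <- rbind(tokA[, c("id", "form", "lemma")], tokB[, c("id", "form", "lemma")])
  posA <- nrow(tokA)
  p1 <- if (s1 == a) match(e1, tokA$id) else posA + match(e1, tokB$id)
  p2 <- if (s2 == a) match(e2, tokA$id) else posA + match(e2, tokB$id)
  new_relation_instance(merged, focus = c(v1, v2), label = label,
                        level = "cross", doc_id = doc$id,
                        sentences = c(a, b), concepts = c(C, D),
                        linear_tokens = tok, linear_e1 = p1, linear_e2 = p2)
}

ppi_instances <- function(doc, graphs, w_path, w_default) {
  ent <- doc$entities
  out <- list()
  for (r in seq_len(nrow(doc$pairs))) {
    p <- doc$pairs[r, ]
    m1 <- ent[ent$mention == p$e1, ]
    m2 <- ent[ent$mention == p$e2, ]
    label <- if (isTRUE(p$label)) "positive" else "negative"
    if (m1$head_token == m2$head_token) next  # preprocessing collapsed pair
    out[[length(out) + 1L]] <- sentence_instance(
      doc, graphs, m1$sentence, m1$head_token, m2$head_token,
      p$e1, p$e2, label, w_path, w_default)
  }
  out
}
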
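fig1_sentence <- function() {
  toy_sentence(
    lemmas = c("seizures", "were", "caused", "by", "alcohol", "and", "fatigue"),
    heads = c(3L, 3L, 0L, 5L, 3L, 5L, 3L),
    labels = c("nsubj", "auxpass", "root", "case", "nmod:by", "cc", "nmod:by"))
}

test_that("the enhanced worked-example graph has 7 vertices and an undirected cycle", {
  s <- fig1_sentence()
  s$deps <- rbind(s$deps,
                  data.frame(head = 5L, dep = 7L, label = "conj:and"))
  g <- build_dep_graph(s)
  expect_equal(nrow(g$vertices), 7L)
  expect_equal(nrow(g$edges), 7L)
  expect_true(all(g$edges$weight == 0.3))
  expect_equal(g$roots, 3L)
  # cycle caused(3) - alcohol(5) - fatigue(7) - caused: removing any one of
  # the three involved edges still leaves 3 and 7 connected
  expect_false(is.null(shortest_path(g, 3L, 7L)))
  drop_edge <- function(g, i) { g$edges <- g$edges[-i, ]; g }
  i_cycle <- which(g$edges$from == 3L & g$edges$to == 7L)
  expect_false(is.null(shortest_path(drop_edge(g, i_cycle), 3L, 7L)))
})

test_that("single-token and chain sentences build degenerate graphs", {
  g1 <- build_dep_graph(toy_sentence("hello", 0L, "root"))
  expect_equal(nrow(g1$vertices), 1L)
  expect_equal(nrow(g1$edges), 0L)
  g3 <- build_dep_graph(toy_sentence(c("a", "b", "c"), c(0L, 1L, 2L),
                                     c("root", "dep", "dep")))
  expect_true(all(g3$edges$weight == 0.3))
})

test_that("entity-path edges get 0.9 and the rest keep 0.3", {
  f <- fig1_fixture()
  g <- f$graph
  hot <- g$edges[g$edges$weight == 0.9, ]
  expect_equal(nrow(hot), 2L)
  expect_setequal(hot$label, c("nsubj", "nmod:by"))
  expect_setequal(hot$to, c(1L, 7L))  # seizures and fatigue endpoints
  expect_true(all(g$edges$weight[g$edges$weight != 0.9] == 0.3))
})

test_that("assign_edge_weights is idempotent, keeps topology, flags no-path", {
  f <- fig1_fixture()
  g1 <- assign_edge_weights(f$graph, f$e1, f$e2)
  g2 <- assign_edge_weights(g1, f$e1, f$e2)
  expect_equal(g1, g2)
  expect_equal(g1$edges[, c("from", "to", "label")],
               f$graph$edges[, c("from", "to", "label")])
  # same entity twice: nothing reweighted
  g0 <- assign_edge_weights(f$graph, f$e1, f$e1)
  expect_true(all(g0$edges$weight == 0.3))
  # disconnected components: weights unchanged, flag set
  two <- dep_graph(data.frame(id = 1:4, label = c("a", "b", "c", "d"),
                              kind = "token"),
                   data.frame(from = c(1L, 3L), to = c(2L, 4L),
                              label = "dep", weight = 0.3),
                   roots = c(1L, 3L))
  gd <- assign_edge_weights(two, 1L, 4L)
  expect_true(gd$no_path)
  expect_true(all(gd$edges$weight == 0.3))
  expect_error(assign_edge_weights(two, 1L, 99L), "unknown vertex")
})

test_that("focus vertices attach once, asymmetrically, with 0.9 focus edges", {
  f <- fig1_fixture()
  g <- attach_focus_vertices(f$graph, f$e1, f$e2)
  expect_equal(nrow(g$vertices), 9L)
  expect_equal(nrow(g$edges), 9L)
  expect_equal(sum(g$vertices$label == "Entity1"), 1L)
  expect_equal(sum(g$vertices$label == "Entity2"), 1L)
  foc <- g$edges[g$edges$label == "focus", ]
  expect_equal(foc$weight, c(0.9, 0.9))
  expect_error(attach_focus_vertices(g, f$e1, f$e2), "already present")
  # swapped order attaches Entity1 to the other mention
  gswap <- attach_focus_vertices(f$graph, f$e2, f$e1)
  to1 <- function(gr) gr$edges$to[gr$edges$from ==
                                    gr$vertices$id[gr$vertices$label == "Entity1"]]
  expect_false(to1(g) == to1(gswap))
})

test_that("cross-sentence merge adds exactly one SentenceBoundary edge at the roots", {
  s1 <- toy_sentence(c("a", "b", "c"), c(0L, 1L, 1L), c("root", "d1", "d2"))
  s2 <- toy_sentence(c("x", "y", "z"), c(0L, 1L, 2L), c("root", "d3", "d4"))
  g1 <- build_dep_graph(s1); g2 <- build_dep_graph(s2)
  m <- merge_cross_sentence(g1, g2)
  expect_equal(nrow(m$vertices), 6L)
  expect_equal(nrow(m$edges), nrow(g1$edges) + nrow(g2$edges) + 1L)
  sb <- m$edges[m$edges$label == "SentenceBoundary", ]
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$weight, 0.3)
  expect_setequal(m$edges$label,
                  c(g1$edges$label, g2$edges$label, "SentenceBoundary"))
  # weighting an entity pair across the boundary up-weights the boundary edge
  mw <- assign_edge_weights(m, 2L, 5L)  # "b" in s1, "y" in s2
  expect_equal(mw$edges$weight[mw$edges$label == "SentenceBoundary"], 0.9)
  # merged in either order, the undirected topology is isomorphic
  m12 <- merge_cross_sentence(g1, g2)
  m21 <- merge_cross_sentence(g2, g1)
  u12 <- sort(paste(pmin(m12$edges$from, m12$edges$to),
                    pmax(m12$edges$from, m12$edges$to), m12$edges$label))
  # map m21 ids into m12's numbering: g2 kept ids 1..3 -> +3; g1 offset -3
  f21 <- ifelse(m21$edges$from <= 3, m21$edges$from + 3L, m21$edges$from - 3L)
  t21 <- ifelse(m21$edges$to <= 3, m21$edges$to + 3L, m21$edges$to - 3L)
  u21 <- sort(paste(pmin(f21, t21), pmax(f21, t21), m21$edges$label))
  expect_equal(u12, u21)
  expect_error(merge_cross_sentence(dep_graph(data.frame(id = 1L, label = "a",
                                                         kind = "token")),
                                    g2), "root")
})

test_that("PubTator annotations round-trip and assemble into documents", {
  docs <- generate_corpus(gen_config(n_documents = 4, seed = 5))
  pt <- withr::local_tempfile(fileext = ".pubtator")
  cu <- withr::local_tempfile(fileext = ".conllu")
  write_corpus(docs, cu, pt)
  annos <- read_pubtator(pt)
  expect_length(annos, 4L)
  expect_equal(annos[[1]]$text, docs[[1]]$text)
  expect_equal(annos[[2]]$entities$concept, docs[[2]]$entities$concept)
  back <- read_cdr_corpus(pt, cu)
  for (i in seq_along(docs)) {
    expect_equal(back[[i]]$entities$head_token, docs[[i]]$entities$head_token)
    expect_equal(back[[i]]$entities$sentence, docs[[i]]$entities$sentence)
    expect_equal(back[[i]]$relations, docs[[i]]$relations)
  }
})

test_that("unified PPI XML parses entities, pairs and parses", {
  xml <- '<corpus source="toy">
    <document id="d1">
      <sentence id="d1.s0" text="ProtA binds ProtB strongly">
        <entity id="d1.s0.e0" charOffset="0-5" type="Protein" text="ProtA"/>
        <entity id="d1.s0.e1" charOffset="12-17" type="Protein" text="ProtB"/>
        <entity id="d1.s0.e2" charOffset="0-2,12-17" type="Protein" text="ProtA ProtB"/>
        <pair id="d1.s0.p0" e1="d1.s0.e0" e2="d1.s0.e1" interaction="True"/>
        <pair id="d1.s0.p1" e1="d1.s0.e1" e2="d1.s0.e0" interaction="False"/>
        <sentenceanalyses>
          <tokenization>
            <token id="t1" text="ProtA" POS="NN" charOffset="0-5"/>
            <token id="t2" text="binds" POS="VBZ" charOffset="6-11"/>
            <token id="t3" text="ProtB" POS="NN" charOffset="12-17"/>
            <token id="t4" text="strongly" POS="RB" charOffset="18-26"/>
          </tokenization>
          <parses>
            <parse>
              <dependency id="p1" t1="t2" t2="t1" type="nsubj"/>
              <dependency id="p2" t1="t2" t2="t3" type="dobj"/>
              <dependency id="p3" t1="t2" t2="t4" type="advmod"/>
            </parse>
          </parses>
        </sentenceanalyses>
      </sentence>
    </document>
  </corpus>'
  docs <- read_ppi_xml(xml)
  expect_length(docs, 1L)
  d <- docs[[1]]
  expect_equal(nrow(d$pairs), 2L)
  expect_equal(d$pairs$label, c(TRUE, FALSE))
  expect_equal(d$entities$n_spans, c(1L, 1L, 2L))
  ins <- build_instances(d)
  expect_length(ins, 2L)
  expect_equal(vapply(ins, `[[`, "", "label"), c("positive", "negative"))
  expect_true(all(vapply(ins, `[[`, "", "level") == "sentence"))
  # unknown entity reference errors
  bad <- sub('e2="d1.s0.e1" interaction="True"',
             'e2="d1.s0.eX" interaction="True"', xml)
  expect_error(read_ppi_xml(bad), "unknown entity")
  # offset outside the sentence errors
  bad2 <- sub('charOffset="12-17" type="Protein" text="ProtB"',
              'charOffset="12-99" type="Protein" text="ProtB"', xml)
  expect_error(read_ppi_xml(bad2), "outside sentence")
})

test_that("instances partition into sentence-level xor cross-level per pair", {
  docs <- generate_corpus(gen_config(n_documents = 25, seed = 13, noise = 0.2))
  ins <- unlist(lapply(docs, build_instances), recursive = FALSE)
  key <- vapply(ins, function(x) paste(x$doc_id, x$concepts[1], x$concepts[2]), "")
  lev <- vapply(ins, `[[`, "", "level")
  for (k in unique(key))
    expect_length(unique(lev[key == k]), 1L)
  # every instance has exactly one Entity1 and one Entity2 vertex
  for (x in ins) {
    expect_equal(sum(x$graph$vertices$label == "Entity1"), 1L)
    expect_equal(sum(x$graph$vertices$label == "Entity2"), 1L)
  }
})
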
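test_that("label-vertex map pads missing labels with dummies", {
  g1 <- dep_graph(data.frame(id = 1:2, label = c("a", "b"), kind = "token"),
                  data.frame(from = 1L, to = 2L, label = "dep", weight = 0.3))
  g2 <- dep_graph(data.frame(id = 1:2, label = c("b", "c"), kind = "token"),
                  data.frame(from = 1L, to = 2L, label = "dep", weight = 0.3))
  m <- make_label_vertex_map(g1, g2)
  expect_equal(m$vocabulary, c("a", "b", "c"))
  expect_true(is.na(m$map1[["c"]]))   # dummy in g1
  expect_true(is.na(m$map2[["a"]]))   # dummy in g2
  expect_equal(unname(m$map1[c("a", "b")]), c(1L, 2L))
  # identical graphs: no dummies
  m2 <- make_label_vertex_map(g1, g1)
  expect_false(anyNA(c(m2$map1, m2$map2)))
})

test_that("duplicate labels map to the lowest-index bearer", {
  g <- dep_graph(data.frame(id = 1:3, label = c("caused", "x", "caused"),
                            kind = "token"),
                 data.frame(from = c(1L, 2L), to = c(2L, 3L), label = "dep",
                            weight = 0.3))
  m <- make_label_vertex_map(g, g)
  expect_equal(m$map1[["caused"]], 1L)
})

test_that("shortest path on the worked example goes through 'caused'", {
  f <- fig1_fixture()
  p <- shortest_path(f$graph, f$e1, f$e2)
  expect_equal(nrow(p), 2L)
  expect_equal(p$label, c("nsubj", "nmod:by"))
  # first edge walked against its direction (caused -> seizures), second
  # along it (caused -> fatigue)
  expect_equal(p$forward, c(FALSE, TRUE))
  # trivial cases
  expect_equal(nrow(shortest_path(f$graph, f$e1, f$e1)), 0L)
  expect_error(shortest_path(f$graph, f$e1, 99L), "unknown vertex")
})

test_that("BFS path lengths match exhaustive enumeration and igraph", {
  skip_if_not_installed("igraph")
  set.seed(11)
  for (rep in 1:25) {
    g <- random_dep_graph(sample(3:8, 1))
    ids <- g$vertices$id
    ig <- igraph::graph_from_data_frame(
      g$edges[, c("from", "to")], directed = FALSE,
      vertices = data.frame(name = ids))
    for (u in ids) for (v in ids) {
      if (u == v) next
      p <- shortest_path(g, u, v)
      want <- oracle_min_hops(g, u, v)
      ig_d <- igraph::distances(ig, as.character(u), as.character(v))[1, 1]
      if (is.null(p)) {
        expect_equal(want, Inf)
        expect_equal(ig_d, Inf)
      } else {
        expect_equal(nrow(p), want)
        expect_equal(nrow(p), unname(ig_d))
      }
    }
  }
})

test_that("path feature map matches the printed worked example", {
  f <- fig1_fixture()
  phi <- path_feature_map(shortest_path(f$graph, f$e1, f$e2))
  expect_equal(phi[["distance"]], 0.9^2)
  expect_equal(phi[["forward"]], 0.9)
  expect_equal(phi[["backward"]], 0.9)
  expect_equal(phi[["edgelabel:nsubj"]], 0.9)
  expect_equal(phi[["edgelabel:nmod:by"]], 0.9)
  # no other edge-label features
  expect_setequal(names(phi), c("distance", "forward", "backward",
                                "edgelabel:nsubj", "edgelabel:nmod:by"))
})

test_that("feature products follow the three formulas on a single edge", {
  path <- data.frame(from = 1L, to = 2L, label = "conj", weight = 0.3,
                     forward = TRUE)
  phi <- path_feature_map(path)
  expect_equal(unname(phi[c("distance", "forward", "backward",
                            "edgelabel:conj")]),
               c(0.3, 0.3, 1, 0.3))
  # no-path sentinel is the zero vector
  expect_length(path_feature_map(NULL), 0L)
  # empty path has all-1 structural features
  empty <- path_feature_map(shortest_path(fig1_fixture()$graph, 1L, 1L))
  expect_equal(unname(empty), c(1, 1, 1))
})

test_that("feature products agree with literal formula evaluation on random paths", {
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(1:6, 1)
    path <- data.frame(from = seq_len(n), to = seq_len(n) + 1L,
                       label = sample(c("a", "b", "c"), n, replace = TRUE),
                       weight = stats::runif(n, 0.05, 1),
                       forward = sample(c(TRUE, FALSE), n, replace = TRUE))
    phi <- path_feature_map(path)
    expect_equal(phi[["distance"]], prod(path$weight), tolerance = 1e-12)
    expect_equal(phi[["forward"]], prod(path$weight[path$forward]),
                 tolerance = 1e-12)
    expect_equal(phi[["backward"]], prod(path$weight[!path$forward]),
                 tolerance = 1e-12)
    for (l in unique(path$label))
      expect_equal(phi[[paste0("edgelabel:", l)]],
                   prod(path$weight ^ (path$label == l)), tolerance = 1e-12)
  }
})

test_that("ASM kernel on a 3-vertex chain equals the hand-enumerated sum", {
  g <- dep_graph(data.frame(id = 1:3, label = c("a", "b", "c"), kind = "token"),
                 data.frame(from = c(1L, 2L), to = c(2L, 3L), label = "dep",
                            weight = 0.3))
  # literal evaluation over the 6 ordered label pairs
  phi_ab <- c(distance = 0.3, forward = 0.3, backward = 1, dep = 0.3)
  phi_ba <- c(distance = 0.3, forward = 1, backward = 0.3, dep = 0.3)
  phi_ac <- c(distance = 0.09, forward = 0.09, backward = 1, dep = 0.09)
  phi_ca <- c(distance = 0.09, forward = 1, backward = 0.09, dep = 0.09)
  want <- sum(phi_ab^2) + sum(phi_ba^2) + sum(phi_ac^2) + sum(phi_ca^2) +
    sum(phi_ab^2) + sum(phi_ba^2)  # (b,c) and (c,b) mirror (a,b), (b,a)
  expect_equal(asm_kernel(g, g), want, tolerance = 1e-12)
})

test_that("ASM kernel is symmetric, non-negative, zero on disjoint labels", {
  set.seed(31)
  for (rep in 1:10) {
    g1 <- random_dep_graph(sample(3:7, 1))
    g2 <- random_dep_graph(sample(3:7, 1))
    k12 <- asm_kernel(g1, g2)
    expect_equal(k12, asm_kernel(g2, g1), tolerance = 1e-12)
    expect_gte(k12, 0)
  }
  f <- fig1_fixture()$graph
  other <- dep_graph(data.frame(id = 1:2, label = c("p", "q"), kind = "token"),
                     data.frame(from = 1L, to = 2L, label = "dep", weight = 0.3))
  expect_equal(asm_kernel(f, other), 0)
  expect_gt(asm_kernel(f, f), 0)
})

test_that("vocabulary padding with unrelated labels never changes kernel values", {
  set.seed(41)
  g1 <- random_dep_graph(5)
  g2 <- random_dep_graph(6)
  k <- asm_kernel(g1, g2)
  # add isolated vertices with fresh labels to both graphs
  pad <- function(g, labs) {
    g$vertices <- rbind(g$vertices,
                        data.frame(id = max(g$vertices$id) + seq_along(labs),
                                   label = labs, kind = "dummy"))
    g
  }
  expect_equal(asm_kernel(pad(g1, c("zz1", "zz2")), g2), k)
  expect_equal(asm_kernel(pad(g1, "zz1"), pad(g2, "qq7")), k)
})

test_that("lowering a used path edge weight cannot increase the distance feature", {
  f <- fig1_fixture()
  p <- shortest_path(f$graph, f$e1, f$e2)
  d0 <- path_feature_map(p)[["distance"]]
  g2 <- f$graph
  g2$edges$weight[g2$edges$label == "nsubj"] <- 0.5
  d1 <- path_feature_map(shortest_path(g2, f$e1, f$e2))[["distance"]]
  expect_lt(d1, d0)
})

test_that("cosine-normalized ASM kernel is 1 on itself and symmetric in [0,1]", {
  f <- fig1_fixture()$graph
  expect_equal(asm_normalized(f, f), 1)
  g2 <- dep_graph(data.frame(id = 1:2, label = c("seizures", "x"), kind = "token"),
                  data.frame(from = 1L, to = 2L, label = "nsubj", weight = 0.3))
  v <- asm_normalized(f, g2)
  expect_equal(v, asm_normalized(g2, f), tolerance = 1e-12)
  expect_gte(v, 0); expect_lte(v, 1)
})
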
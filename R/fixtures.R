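#' Worked-example fixture: "Seizures were caused by Alcohol and Fatigue"
#'
#' The enhanced dependency graph of this sentence is the standard worked
#' example for the edge-weighted ASM kernel: seven token vertices, seven
#' edges (`nsubj`, `auxpass`, `case`, `nmod:by` twice, `cc`, `conj:and`),
#' whose undirected form contains a cycle through "caused", "alcohol" and
#' "fatigue" (enhanced parses propagate conjunct dependents). Weights are
#' already assigned for the entity pair (seizures, fatigue): the two edges
#' on their shortest path - `nsubj(caused, seizures)` and
#' `nmod:by(caused, fatigue)` - carry 0.9, the rest 0.3.
#'
#' @return A list with `graph` (the weighted [dep_graph()]), `e1`, `e2`
#'   (vertex ids of seizures and fatigue).
#' @export
fig1_fixture <- function() {
  lemmas <- c("seizures", "were", "caused", "by", "alcohol", "and", "fatigue")
  vertices <- data.frame(id = 1:7, label = lemmas, kind = "token",
                         stringsAsFactors = FALSE)
  edges <- data.frame(
    from = c(3L, 3L, 5L, 3L, 5L, 5L, 3L),
    to = c(1L, 2L, 4L, 5L, 6L, 7L, 7L),
    label = c("nsubj", "auxpass", "case", "nmod:by", "cc", "conj:and", "nmod:by"),
    weight = 0.3, stringsAsFactors = FALSE)
  g <- dep_graph(vertices, edges, roots = 3L)
  g <- assign_edge_weights(g, 1L, 7L)
  list(graph = g, e1 = 1L, e2 = 7L)
}

#' Sample annotated CDR document fixture
#'
#' The standard illustration of an annotated PubMed abstract for
#' chemical-induced disease extraction: title
#' "Propylthiouracil-induced hepatic damage", five entity mentions of three
#' concepts (chemical D011441; diseases D056486 and D006521) at their
#' printed document offsets, and two gold relations. The pair
#' (D011441, D056486) co-occurs in the title and the first abstract
#' sentence (sentence-level); "chronic active hepatitis" (D006521) shares
#' no sentence with any chemical mention, so (D011441, D006521) is a
#' cross-sentence relation. The bundled dependency parses of the three
#' sentences are hand-written fixture data.
#'
#' @return A `document`.
#' @export
table1_fixture <- function() {
  title <- "Propylthiouracil-induced hepatic damage"
  abstract <- paste0(
    "Two cases of propylthiouracil-induced liver damage have been observed. ",
    "The first case is of an acute type of damage, proven by rechallenge; ",
    "the second presents a clinical and histologic picture resembling ",
    "chronic active hepatitis, with spontaneous remission.")
  # two-char separator keeps the printed mention offsets (54-70, 246-270...)
  text <- paste0(title, "\n\n", abstract)

  s_title <- fixture_sentence(
    forms = c("Propylthiouracil-induced", "hepatic", "damage"),
    lemmas = c("propylthiouracil-induced", "hepatic", "damage"),
    upos = c("ADJ", "ADJ", "NOUN"),
    heads = c(3L, 3L, 0L),
    labels = c("amod", "amod", "root"))
  s1 <- fixture_sentence(
    forms = c("Two", "cases", "of", "propylthiouracil-induced", "liver",
              "damage", "have", "been", "observed", "."),
    lemmas = c("two", "case", "of", "propylthiouracil-induced", "liver",
               "damage", "have", "be", "observe", "."),
    upos = c("NUM", "NOUN", "ADP", "ADJ", "NOUN", "NOUN", "AUX", "AUX",
             "VERB", "PUNCT"),
    heads = c(2L, 9L, 6L, 6L, 6L, 2L, 9L, 9L, 0L, 9L),
    labels = c("nummod", "nsubjpass", "case", "amod", "compound", "nmod:of",
               "aux", "auxpass", "root", "punct"))
  s2 <- fixture_sentence(
    forms = c("The", "first", "case", "is", "of", "an", "acute", "type",
              "of", "damage", ",", "proven", "by", "rechallenge", ";",
              "the", "second", "presents", "a", "clinical", "and",
              "histologic", "picture", "resembling", "chronic", "active",
              "hepatitis", ",", "with", "spontaneous", "remission", "."),
    lemmas = c("the", "first", "case", "be", "of", "a", "acute", "type",
               "of", "damage", ",", "prove", "by", "rechallenge", ";",
               "the", "second", "present", "a", "clinical", "and",
               "histologic", "picture", "resemble", "chronic", "active",
               "hepatitis", ",", "with", "spontaneous", "remission", "."),
    upos = c("DET", "ADJ", "NOUN", "AUX", "ADP", "DET", "ADJ", "NOUN",
             "ADP", "NOUN", "PUNCT", "VERB", "ADP", "NOUN", "PUNCT",
             "DET", "ADJ", "VERB", "DET", "ADJ", "CCONJ", "ADJ", "NOUN",
             "VERB", "ADJ", "ADJ", "NOUN", "PUNCT", "ADP", "ADJ", "NOUN",
             "PUNCT"),
    heads = c(3L, 3L, 4L, 0L, 8L, 8L, 8L, 4L, 10L, 8L, 4L, 10L, 14L, 12L,
              4L, 17L, 18L, 4L, 23L, 23L, 22L, 20L, 18L, 23L, 27L, 27L,
              24L, 18L, 31L, 31L, 18L, 4L),
    labels = c("det", "amod", "nsubj", "root", "case", "det", "amod",
               "nmod:of", "case", "nmod:of", "punct", "acl", "case",
               "nmod:by", "punct", "det", "amod", "conj", "det", "amod",
               "cc", "amod", "dobj", "acl", "amod", "amod", "dobj",
               "punct", "case", "amod", "nmod:with", "punct"))

  anno <- list(
    id = "fixture-cdr-1", title = title, abstract = abstract,
    entities = data.frame(
      start = c(0L, 54L, 25L, 79L, 246L),
      end = c(16L, 70L, 39L, 91L, 270L),
      text = c("Propylthiouracil", "propylthiouracil", "hepatic damage",
               "liver damage", "chronic active hepatitis"),
      type = c("Chemical", "Chemical", "Disease", "Disease", "Disease"),
      concept = c("D011441", "D011441", "D056486", "D056486", "D006521"),
      stringsAsFactors = FALSE),
    relations = data.frame(c1 = c("D011441", "D011441"),
                           c2 = c("D006521", "D056486"),
                           stringsAsFactors = FALSE))
  anno$text <- text
  assemble_document(anno, list(s_title, s1, s2))
}

fixture_sentence <- function(forms, lemmas, upos, heads, labels) {
  list(tokens = data.frame(id = seq_along(forms), form = forms,
                           lemma = lemmas, upos = upos, misc = "_",
                           stringsAsFactors = FALSE),
       deps = data.frame(head = heads, dep = seq_along(forms),
                         label = labels, stringsAsFactors = FALSE),
       meta = character(), enhanced = FALSE)
}
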
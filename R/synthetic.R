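#' Synthetic corpus generator configuration
#'
#' The generator emulates CDR-style annotated abstracts: multi-sentence
#' documents with one chemical and one disease concept each, random
#' head-outward dependency trees (each token attaches to a uniformly random
#' earlier token), occasional enhanced-dependency extra edges that create
#' undirected cycles, and a plantable lexical-structural signal mimicking
#' how chemical-induced-disease relations are actually expressed ("X induces
#' Y"): for a positive pair, a trigger lemma is planted on the dependency
#' path between the two mentions - in the same-sentence case the trigger
#' token becomes the direct syntactic governor of both mentions
#' (`nsubj`/`dobj`); in the cross-sentence case the trigger is planted on
#' one sentence's root (which always lies on the merged path) with that
#' sentence's mention attached directly under it. Negatives are placed
#' randomly and never contain a trigger, so a rule-based path-trigger
#' detector upper-bounds the kernels at F1 = 1 when `noise = 0`.
#'
#' Entity mentions are blinded to the shared type lemmas `"chemical"` and
#' `"disease"`, the standard preprocessing for relation extraction (concept
#' identity stays in the annotation, not the text).
#'
#' @param n_documents number of documents (one candidate pair each).
#' @param sentences_range,tokens_range inclusive ranges for sentences per
#'   document and tokens per sentence.
#' @param vocab_size filler lemma vocabulary size.
#' @param dep_labels dependency label vocabulary.
#' @param triggers trigger lemma set planted on positive paths.
#' @param p_positive probability a document's pair is related.
#' @param p_cross probability the two mentions are split across sentences.
#' @param noise probability a positive pair lacks its trigger.
#' @param p_extra_edge per-sentence probability of one extra enhanced edge.
#' @param seed RNG seed; generation is a pure function of the config.
#' @return A `gen_config`.
#' @export
gen_config <- function(n_documents = 20, sentences_range = c(2, 4),
                       tokens_range = c(6, 10), vocab_size = 500,
                       dep_labels = c("nsubj", "dobj", "nmod:by", "conj:and",
                                      "case", "amod", "advmod"),
                       triggers = c("induce", "cause"),
                       p_positive = 0.35, p_cross = 0.3, noise = 0,
                       p_extra_edge = 0.15, seed = 1) {
  stopifnot(n_documents >= 1, diff(sentences_range) >= 0, sentences_range[1] >= 1,
            tokens_range[1] >= 4, vocab_size > length(triggers),
            p_positive >= 0, p_positive <= 1, p_cross >= 0, p_cross <= 1,
            noise >= 0, noise <= 1)
  structure(list(n_documents = n_documents, sentences_range = sentences_range,
                 tokens_range = tokens_range, vocab_size = vocab_size,
                 dep_labels = dep_labels, triggers = triggers,
                 p_positive = p_positive, p_cross = p_cross, noise = noise,
                 p_extra_edge = p_extra_edge, seed = seed),
            class = "gen_config")
}

#' Generate a synthetic CDR-style corpus
#'
#' @param config a [gen_config()].
#' @return A list of `document` objects (see [assemble_document()] for the
#'   shape), each carrying one chemical and one disease mention and a gold
#'   relation iff the pair is positive.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "gen_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  vocab <- setdiff(sprintf("w%03d", seq_len(config$vocab_size)), config$triggers)
  lapply(seq_len(config$n_documents), function(i) gen_document(i, config, vocab))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

gen_document <- function(i, cfg, vocab) {
  doc_id <- sprintf("SYN%05d", i)
  chem_concept <- sprintf("C%05d", i); chem_lemma <- "chemical"
  dis_concept <- sprintf("D%05d", i); dis_lemma <- "disease"
  n_s <- sample_range(cfg$sentences_range)
  sents <- lapply(seq_len(n_s), function(s)
    gen_sentence(sample_range(cfg$tokens_range), cfg, vocab))

  positive <- stats::runif(1) < cfg$p_positive
  cross <- n_s >= 2 && stats::runif(1) < cfg$p_cross
  plant <- positive && stats::runif(1) >= cfg$noise

  if (!cross) {
    s <- sample.int(n_s, 1)
    placed <- place_same_sentence(sents[[s]], chem_lemma, dis_lemma, plant, cfg)
    sents[[s]] <- placed$sentence
    mention <- data.frame(sentence = c(s, s), token = c(placed$t1, placed$t2))
  } else {
    ss <- sort(sample.int(n_s, 2))
    n1 <- nrow(sents[[ss[1]]]$tokens); n2 <- nrow(sents[[ss[2]]]$tokens)
    t1 <- sample(2:n1, 1); t2 <- sample(2:n2, 1)
    sents[[ss[1]]]$tokens$lemma[t1] <- chem_lemma
    sents[[ss[2]]]$tokens$lemma[t2] <- dis_lemma
    if (plant) {
      # sentence roots always lie on the merged path; a planted
      # cross-sentence relation makes both mentions main arguments of
      # their sentences' head predicates and one head the causal trigger
      host <- sample(ss, 1)
      sents[[host]]$tokens$lemma[1L] <- sample(cfg$triggers, 1)
      sents[[ss[1]]] <- reattach(sents[[ss[1]]], t1, 1L, "nsubj")
      sents[[ss[2]]] <- reattach(sents[[ss[2]]], t2, 1L, "dobj")
    }
    mention <- data.frame(sentence = ss, token = c(t1, t2))
  }

  sents <- finalize_sentences(sents, doc_id)
  offs <- token_offsets(sents)
  ent <- data.frame(
    start = mapply(function(s, t) offs[[s]]$start[t], mention$sentence, mention$token),
    end = mapply(function(s, t) offs[[s]]$end[t], mention$sentence, mention$token),
    text = c(chem_lemma, dis_lemma),
    type = c("Chemical", "Disease"),
    concept = c(chem_concept, dis_concept),
    sentence = mention$sentence,
    head_token = mention$token, stringsAsFactors = FALSE)
  relations <- if (positive)
    data.frame(c1 = chem_concept, c2 = dis_concept, stringsAsFactors = FALSE)
  else data.frame(c1 = character(), c2 = character(), stringsAsFactors = FALSE)

  texts <- vapply(sents, function(s) paste(s$tokens$form, collapse = " "), "")
  for (s in seq_along(sents)) {
    sents[[s]]$tokens$start <- offs[[s]]$start
    sents[[s]]$tokens$end <- offs[[s]]$end
    sents[[s]]$span <- c(offs[[s]]$start[1L], offs[[s]]$end[length(offs[[s]]$end)])
  }
  structure(list(id = doc_id, title = texts[1L],
                 abstract = paste(texts[-1L], collapse = " "),
                 text = paste(texts, collapse = " "),
                 sentences = sents, entities = ent, relations = relations),
            class = "document")
}

sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)

gen_sentence <- function(n_t, cfg, vocab) {
  lemma <- sample(vocab, n_t, replace = TRUE)
  head <- c(0L, vapply(2:n_t, function(i) sample.int(i - 1L, 1L), integer(1)))
  label <- c("root", sample(cfg$dep_labels, n_t - 1L, replace = TRUE))
  deps <- data.frame(head = head, dep = seq_len(n_t), label = label,
                     stringsAsFactors = FALSE)
  enhanced <- FALSE
  if (stats::runif(1) < cfg$p_extra_edge) {
    for (try in 1:10) {
      uv <- sample.int(n_t, 2)
      lab <- sample(cfg$dep_labels, 1)
      dup <- any(deps$head == uv[1] & deps$dep == uv[2] & deps$label == lab)
      if (!dup && uv[2] != 1L) {
        deps <- rbind(deps, data.frame(head = uv[1], dep = uv[2], label = lab,
                                       stringsAsFactors = FALSE))
        enhanced <- TRUE
        break
      }
    }
  }
  list(tokens = data.frame(id = seq_len(n_t), form = lemma, lemma = lemma,
                           upos = sample(c("NOUN", "VERB", "ADJ"), n_t,
                                         replace = TRUE),
                           misc = "_", stringsAsFactors = FALSE),
       deps = deps, meta = character(), enhanced = enhanced)
}

# Mention placement within one sentence. A planted positive mimics
# "X induces Y": the trigger token becomes the direct governor of both
# mentions (nsubj/dobj), so the entity shortest path is mention-trigger-
# mention. Otherwise the two mentions are placed at random positions whose
# shortest path has at least one intermediate vertex (structural parity
# with planted pairs, which always have the trigger in between).
place_same_sentence <- function(sentence, chem_lemma, dis_lemma, plant, cfg) {
  n_t <- nrow(sentence$tokens)
  if (plant) {
    g <- sample.int(n_t - 2L, 1)
    ts <- g + sample.int(n_t - g, 2)
    sentence$tokens$lemma[g] <- sample(cfg$triggers, 1)
    sentence <- reattach(sentence, ts[1], g, "nsubj")
    sentence <- reattach(sentence, ts[2], g, "dobj")
    # an enhanced extra edge joining the two mentions would shortcut the
    # path past the trigger; drop it
    keep <- !(sentence$deps$head %in% ts & sentence$deps$dep %in% ts)
    sentence$deps <- sentence$deps[keep, , drop = FALSE]
    sentence$tokens$lemma[ts[1]] <- chem_lemma
    sentence$tokens$lemma[ts[2]] <- dis_lemma
    sentence$tokens$form <- sentence$tokens$lemma
    return(list(sentence = sentence, t1 = ts[1], t2 = ts[2]))
  }
  graph <- build_dep_graph(sentence)
  for (try in 1:50) {
    ts <- sample(2:n_t, 2)
    res <- bfs_path(graph, ts[1], ts[2])
    if (!is.null(res) && length(res$vertices) >= 3L) {
      sentence$tokens$lemma[ts[1]] <- chem_lemma
      sentence$tokens$lemma[ts[2]] <- dis_lemma
      sentence$tokens$form <- sentence$tokens$lemma
      return(list(sentence = sentence, t1 = ts[1], t2 = ts[2]))
    }
  }
  stop("could not place a mention pair with an intermediate path vertex")
}

# Re-point token t's head to g (g earlier in the sentence, so the tree stays
# a tree: descendants always have larger indices than their head under
# sequential attachment). Drops any enhanced extra edge that would
# duplicate the new (g, t, rel) triple.
reattach <- function(sentence, t, g, rel) {
  deps <- sentence$deps
  tree_row <- which(deps$dep == t)[1L]
  deps$head[tree_row] <- g
  deps$label[tree_row] <- rel
  dup <- duplicated(deps[, c("head", "dep", "label")])
  sentence$deps <- deps[!dup, , drop = FALSE]
  sentence
}

finalize_sentences <- function(sents, doc_id) {
  for (s in seq_along(sents)) {
    sents[[s]]$tokens$form <- sents[[s]]$tokens$lemma
    sents[[s]]$meta <- c(doc_id = doc_id,
                         sent_id = sprintf("%s.s%d", doc_id, s),
                         text = paste(sents[[s]]$tokens$lemma, collapse = " "))
  }
  sents
}

# 0-based half-open offsets of every token when sentences are joined by
# single spaces (matching the PubTator text convention).
token_offsets <- function(sents) {
  pos <- 0L
  out <- vector("list", length(sents))
  for (s in seq_along(sents)) {
    n <- nchar(sents[[s]]$tokens$form)
    start <- integer(length(n)); end <- integer(length(n))
    for (t in seq_along(n)) {
      start[t] <- pos; end[t] <- pos + n[t]
      pos <- end[t] + 1L
    }
    out[[s]] <- list(start = start, end = end)
  }
  out
}

#' Write a generated corpus to PubTator + CoNLL-U files
#'
#' Round-trips through [read_cdr_corpus()], exercising the full file-based
#' pipeline.
#'
#' @param docs documents from [generate_corpus()].
#' @param conllu_path,pubtator_path output paths.
#' @export
write_corpus <- function(docs, conllu_path, pubtator_path) {
  write_pubtator(docs, pubtator_path)
  sents <- unlist(lapply(docs, `[[`, "sentences"), recursive = FALSE)
  write_conllu(sents, conllu_path)
  invisible(list(conllu = conllu_path, pubtator = pubtator_path))
}

#' Rule-based path-trigger detector
#'
#' Labels an instance positive iff a trigger lemma occurs on the shortest
#' path between its two focus entities. On noise-free synthetic corpora this
#' oracle attains F1 = 1, upper-bounding what the kernels can learn.
#'
#' @param instance a `relation_instance`.
#' @param triggers trigger lemma set.
#' @return `"positive"` or `"negative"`.
#' @export
detect_trigger <- function(instance, triggers = c("induce", "cause")) {
  res <- bfs_path(instance$graph, instance$focus[1], instance$focus[2])
  if (is.null(res)) return("negative")
  labs <- vertex_label(instance$graph, res$vertices)
  if (any(labs %in% triggers)) "positive" else "negative"
}
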
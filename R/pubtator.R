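#' Read PubTator-style document annotations
#'
#' The PubTator format carries, per document: a title line `pmid|t|...`, an
#' abstract line `pmid|a|...`, one tab-separated mention line per entity
#' (`pmid start end text type concept`) and relation lines
#' (`pmid CID chemical disease`). Offsets are 0-based half-open into the
#' document text `title + " " + abstract`.
#'
#' @param path path to a PubTator file, or a character vector of lines.
#' @return A list of annotation records, each with `id`, `title`, `abstract`,
#'   `text`, `entities` (data.frame `start`, `end`, `text`, `type`,
#'   `concept`) and `relations` (data.frame `c1`, `c2`).
#' @export
read_pubtator <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path))
    readLines(path, warn = FALSE) else unlist(strsplit(path, "\n", fixed = TRUE))
  docs <- list(); cur <- NULL
  new_doc <- function(id) list(
    id = id, title = "", abstract = "",
    entities = data.frame(start = integer(), end = integer(), text = character(),
                          type = character(), concept = character(),
                          stringsAsFactors = FALSE),
    relations = data.frame(c1 = character(), c2 = character(),
                           stringsAsFactors = FALSE))
  push <- function() {
    if (!is.null(cur)) {
      cur$text <<- paste(cur$title, cur$abstract, sep = " ")
      docs[[length(docs) + 1L]] <<- cur
    }
    cur <<- NULL
  }
  for (line in lines) {
    if (!nzchar(trimws(line))) { push(); next }
    if (grepl("^[^\t|]+\\|[ta]\\|", line)) {
      m <- regmatches(line, regexec("^([^|]+)\\|([ta])\\|(.*)$", line))[[1]]
      if (is.null(cur)) cur <- new_doc(m[2])
      if (m[3] == "t") cur$title <- m[4] else cur$abstract <- m[4]
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (is.null(cur)) cur <- new_doc(f[1])
    if (length(f) >= 4L && f[2] == "CID") {
      cur$relations <- rbind(cur$relations,
                             data.frame(c1 = f[3], c2 = f[4], stringsAsFactors = FALSE))
    } else if (length(f) >= 6L) {
      cur$entities <- rbind(cur$entities, data.frame(
        start = as.integer(f[2]), end = as.integer(f[3]), text = f[4],
        type = f[5], concept = f[6], stringsAsFactors = FALSE))
    } else {
      stop("malformed PubTator line: ", line)
    }
  }
  push()
  docs
}

#' Write annotation records to PubTator format
#'
#' @param docs list of annotation records (see [read_pubtator()]) or of full
#'   documents from [assemble_document()] / [generate_corpus()].
#' @param path output file path.
#' @export
write_pubtator <- function(docs, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (d in docs) {
    writeLines(sprintf("%s|t|%s", d$id, d$title), con)
    writeLines(sprintf("%s|a|%s", d$id, d$abstract), con)
    ent <- d$entities
    for (r in seq_len(nrow(ent)))
      writeLines(paste(d$id, ent$start[r], ent$end[r], ent$text[r],
                       ent$type[r], ent$concept[r], sep = "\t"), con)
    rel <- d$relations
    for (r in seq_len(nrow(rel)))
      writeLines(paste(d$id, "CID", rel$c1[r], rel$c2[r], sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}

# Locate each token of each sentence inside the document text by sequential
# scanning (tokens appear in order; whitespace between them is arbitrary).
# Adds start/end columns to every token table and a span to each sentence.
align_sentences <- function(text, sentences) {
  cursor <- 1L
  for (si in seq_along(sentences)) {
    tok <- sentences[[si]]$tokens
    starts <- ends <- integer(nrow(tok))
    for (r in seq_len(nrow(tok))) {
      hit <- regexpr(tok$form[r], substr(text, cursor, nchar(text)), fixed = TRUE)
      if (hit < 0)
        stop(sprintf("cannot align token '%s' of sentence %d in document text",
                     tok$form[r], si))
      starts[r] <- cursor + hit - 2L          # 0-based
      ends[r] <- starts[r] + nchar(tok$form[r])
      cursor <- ends[r] + 1L                  # 1-based cursor past the token
    }
    tok$start <- starts; tok$end <- ends
    sentences[[si]]$tokens <- tok
    sentences[[si]]$span <- c(starts[1L], ends[length(ends)])
  }
  sentences
}

#' Assemble a full document from annotations and parses
#'
#' Combines one PubTator annotation record with its sentences' dependency
#' parses into a `document`: token character offsets are recovered by
#' aligning each sentence's tokens against the document text, and every
#' entity mention is assigned its sentence index and head token.
#'
#' The head token of a multi-token mention is the unique mention token whose
#' syntactic head lies outside the mention; if no such unique token exists,
#' the last token of the mention is used.
#'
#' @param anno an annotation record from [read_pubtator()].
#' @param sentences parsed sentences of the document, in order, as returned
#'   by [read_conllu()].
#' @return An object of class `document` with fields `id`, `title`,
#'   `abstract`, `text`, `sentences`, `entities` (with `sentence` and
#'   `head_token` columns) and `relations`.
#' @export
assemble_document <- function(anno, sentences) {
  sentences <- align_sentences(anno$text, sentences)
  spans <- t(vapply(sentences, function(s) s$span, numeric(2)))
  ent <- anno$entities
  ent$sentence <- NA_integer_; ent$head_token <- NA_integer_
  for (r in seq_len(nrow(ent))) {
    si <- which(ent$start[r] >= spans[, 1] & ent$start[r] < spans[, 2])
    if (!length(si))
      stop(sprintf("mention '%s' [%d,%d) outside every sentence span",
                   ent$text[r], ent$start[r], ent$end[r]))
    si <- si[1L]
    tok <- sentences[[si]]$tokens
    in_mention <- tok$start < ent$end[r] & tok$end > ent$start[r]
    if (!any(in_mention))
      stop(sprintf("mention '%s' covers no token", ent$text[r]))
    ent$sentence[r] <- si
    ent$head_token[r] <- mention_head(tok$id[in_mention], sentences[[si]]$deps)
  }
  structure(list(id = anno$id, title = anno$title, abstract = anno$abstract,
                 text = anno$text, sentences = sentences, entities = ent,
                 relations = anno$relations),
            class = "document")
}

mention_head <- function(token_ids, deps) {
  heads <- deps$head[match(token_ids, deps$dep)]
  outside <- token_ids[!(heads %in% token_ids)]
  if (length(outside) == 1L) outside else token_ids[length(token_ids)]
}

#' Read a CDR-style corpus (PubTator annotations + CoNLL-U parses)
#'
#' Sentences in the CoNLL-U file are attached to documents via their
#' `# doc_id = <id>` comment, in file order.
#'
#' @param pubtator_path PubTator annotation file.
#' @param conllu_path CoNLL-U file whose sentences carry `# doc_id` comments.
#' @return A list of `document` objects.
#' @export
read_cdr_corpus <- function(pubtator_path, conllu_path) {
  annos <- read_pubtator(pubtator_path)
  sents <- read_conllu(conllu_path)
  doc_ids <- vapply(sents, function(s) unname(s$meta["doc_id"]), character(1))
  if (anyNA(doc_ids))
    stop("every CoNLL-U sentence needs a '# doc_id = ...' comment")
  lapply(annos, function(a)
    assemble_document(a, sents[doc_ids == a$id]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.document <- function(x, ...) {
  cat(sprintf("<document %s: %d sentence(s), %d mention(s), %d gold relation(s)>\n",
              x$id, length(x$sentences), nrow(x$entities), nrow(x$relations)))
  invisible(x)
}
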
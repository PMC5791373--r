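#' Read a unified-format PPI corpus
#'
#' Reads the standardized XML dialect used to distribute the five
#' protein-protein interaction corpora (AIMed, BioInfer, HPRD50, IEPA, LLL):
#' `corpus > document > sentence` with `entity` (character offsets),
#' `pair` (candidate protein pairs labelled `interaction="True"/"False"`)
#' and bundled `token` / `dependency` analysis elements. Offsets of the form
#' `"a-b"` are taken as 0-based half-open `[a, b)`; discontinuous offsets
#' (`"a-b,c-d"`) produce multi-span mentions.
#'
#' @param path path to the XML file (or a literal XML string).
#' @return A list of `document` objects. Candidate pairs are exposed in each
#'   document's `pairs` data.frame (`e1`, `e2`, `label`, `sentence`), which
#'   [build_instances()] turns into labelled sentence-level instances.
#' @export
read_ppi_xml <- function(path) {
  xml <- xml2::read_xml(path)
  docs <- list()
  for (dnode in xml2::xml_find_all(xml, ".//document")) {
    did <- xml2::xml_attr(dnode, "id")
    sentences <- list(); entities <- NULL; pairs <- NULL
    texts <- character()
    snodes <- xml2::xml_find_all(dnode, ".//sentence")
    for (si in seq_along(snodes)) {
      sn <- snodes[[si]]
      sid <- xml2::xml_attr(sn, "id")
      stext <- xml2::xml_attr(sn, "text")
      texts <- c(texts, stext)

      tnodes <- xml2::xml_find_all(sn, ".//token")
      tokens <- data.frame(
        id = seq_along(tnodes),
        xml_id = xml2::xml_attr(tnodes, "id"),
        form = xml2::xml_attr(tnodes, "text"),
        lemma = tolower(xml2::xml_attr(tnodes, "text")),
        upos = xml2::xml_attr(tnodes, "POS") %||na% "_",
        stringsAsFactors = FALSE)
      toff <- do.call(rbind, lapply(xml2::xml_attr(tnodes, "charOffset"),
                                    function(x) parse_char_offset(x)[1L, ]))
      tokens$start <- toff$start; tokens$end <- toff$end
      dnodes <- xml2::xml_find_all(sn, ".//dependency")
      deps <- data.frame(
        head = tokens$id[match(xml2::xml_attr(dnodes, "t1"), tokens$xml_id)],
        dep = tokens$id[match(xml2::xml_attr(dnodes, "t2"), tokens$xml_id)],
        label = xml2::xml_attr(dnodes, "type"), stringsAsFactors = FALSE)
      root_ids <- setdiff(tokens$id, deps$dep)   # ungoverned tokens are roots
      if (length(root_ids))
        deps <- rbind(data.frame(head = 0L, dep = root_ids[1L], label = "root",
                                 stringsAsFactors = FALSE), deps)
      sentences[[si]] <- list(tokens = tokens, deps = deps,
                              meta = c(sent_id = sid), enhanced = FALSE)

      for (en in xml2::xml_find_all(sn, ".//entity")) {
        spans <- parse_char_offset(xml2::xml_attr(en, "charOffset"))
        if (any(spans$end > nchar(stext)))
          stop(sprintf("entity offset outside sentence %s", sid))
        covered <- rep(FALSE, nrow(tokens))
        for (k in seq_len(nrow(spans)))
          covered <- covered | (tokens$start < spans$end[k] &
                                tokens$end > spans$start[k])
        if (!any(covered))
          stop(sprintf("entity %s covers no token in sentence %s",
                       xml2::xml_attr(en, "id"), sid))
        entities <- rbind(entities, data.frame(
          mention = xml2::xml_attr(en, "id"),
          concept = xml2::xml_attr(en, "id"),
          type = xml2::xml_attr(en, "type") %||na% "Protein",
          text = xml2::xml_attr(en, "text"), sentence = si,
          start = spans$start[1L], end = spans$end[nrow(spans)],
          head_token = mention_head(tokens$id[covered], deps),
          n_spans = nrow(spans), stringsAsFactors = FALSE))
      }
      for (pn in xml2::xml_find_all(sn, ".//pair")) {
        pairs <- rbind(pairs, data.frame(
          e1 = xml2::xml_attr(pn, "e1"), e2 = xml2::xml_attr(pn, "e2"),
          label = tolower(xml2::xml_attr(pn, "interaction")) == "true",
          sentence = si, stringsAsFactors = FALSE))
      }
    }
    if (!is.null(pairs)) {
      bad <- setdiff(c(pairs$e1, pairs$e2), entities$mention)
      if (length(bad))
        stop("pair references unknown entity id: ", paste(bad, collapse = ", "))
    }
    docs[[length(docs) + 1L]] <- structure(
      list(id = did, title = if (length(texts)) texts[1L] else "",
           abstract = paste(texts[-1L], collapse = " "),
           text = paste(texts, collapse = " "),
           sentences = sentences,
           entities = if (is.null(entities)) empty_entities() else entities,
           relations = data.frame(c1 = character(), c2 = character()),
           pairs = if (is.null(pairs))
             data.frame(e1 = character(), e2 = character(),
                        label = logical(), sentence = integer()) else pairs),
      class = "document")
  }
  docs
}

empty_entities <- function() {
  data.frame(mention = character(), concept = character(), type = character(),
             text = character(), sentence = integer(), start = integer(),
             end = integer(), head_token = integer(), stringsAsFactors = FALSE)
}

# "0-16" or "0-2,10-13" -> data.frame(start, end), 0-based half-open
parse_char_offset <- function(x) {
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+)$", parts))
  if (any(vapply(m, length, integer(1)) != 3L))
    stop("malformed charOffset: ", x)
  data.frame(start = as.integer(vapply(m, `[`, "", 2L)),
             end = as.integer(vapply(m, `[`, "", 3L)))
}

`%||na%` <- function(a, b) ifelse(is.na(a), b, a)
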
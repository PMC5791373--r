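#' Read dependency-parsed sentences from CoNLL-U
#'
#' Parses the standard 10-column CoNLL-U format. When any token in a sentence
#' carries an enhanced-dependency annotation (the DEPS column), the enhanced
#' edge set is used for that sentence and the basic HEAD/DEPREL edges are
#' ignored; enhanced graphs may contain undirected cycles (e.g. propagated
#' conjunct dependents such as `nmod:by`). Multiword-token ranges (`3-4`) and
#' empty nodes (`3.1`) are skipped.
#'
#' @param path path to a CoNLL-U file, or a character vector of lines.
#' @return A list of sentence records, each a list with:
#'   * `tokens`: data.frame `id`, `form`, `lemma`, `upos`, `misc`
#'   * `deps`: data.frame `head`, `dep`, `label` (head 0 = sentence root)
#'   * `meta`: named character vector of `# key = value` comments
#'   * `enhanced`: logical, whether the DEPS column was used
#' @export
read_conllu <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path))
    readLines(path, warn = FALSE) else unlist(strsplit(path, "\n", fixed = TRUE))
  sentences <- list()
  tok_rows <- list(); meta <- character(); enh_rows <- list()
  flush <- function() {
    if (!length(tok_rows)) return(invisible())
    tokens <- do.call(rbind, tok_rows)
    use_enh <- any(!vapply(enh_rows, is.null, logical(1)))
    if (use_enh) {
      deps <- do.call(rbind, Filter(Negate(is.null), enh_rows))
    } else {
      deps <- data.frame(head = tokens$head, dep = tokens$id,
                         label = tokens$deprel, stringsAsFactors = FALSE)
      check_acyclic_heads(tokens)
    }
    deps <- unique(deps[!is.na(deps$head), , drop = FALSE])
    rownames(deps) <- NULL
    tokens$head <- tokens$deprel <- NULL
    sentences[[length(sentences) + 1L]] <<- list(
      tokens = tokens, deps = deps, meta = meta, enhanced = use_enh)
    tok_rows <<- list(); meta <<- character(); enh_rows <<- list()
    invisible()
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) { flush(); next }
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*([^=]+?)\\s*=\\s*(.*)$", line))[[1]]
      if (length(m) == 3L) meta[m[2]] <- m[3]
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 10L)
      stop(sprintf("malformed CoNLL-U line %d: expected 10 fields, got %d",
                   i, length(f)))
    if (grepl("-", f[1], fixed = TRUE) || grepl(".", f[1], fixed = TRUE)) next
    id <- suppressWarnings(as.integer(f[1]))
    head <- suppressWarnings(as.integer(f[7]))
    if (is.na(id) || (is.na(head) && f[7] != "_"))
      stop(sprintf("malformed CoNLL-U line %d: bad ID or HEAD field", i))
    tok_rows[[length(tok_rows) + 1L]] <- data.frame(
      id = id, form = f[2], lemma = tolower(f[3]), upos = f[4],
      head = head, deprel = f[8], misc = f[10], stringsAsFactors = FALSE)
    enh_rows[[length(enh_rows) + 1L]] <-
      if (f[9] != "_") parse_deps_field(f[9], id, i) else NULL
  }
  flush()
  sentences
}

# DEPS field: head:rel pairs separated by "|"; rel itself may contain ":"
# (e.g. "3:nmod:by"), so split on the first colon only.
parse_deps_field <- function(field, dep_id, line_no) {
  parts <- strsplit(field, "|", fixed = TRUE)[[1]]
  head <- suppressWarnings(as.integer(sub(":.*$", "", parts)))
  if (anyNA(head))
    stop(sprintf("malformed CoNLL-U line %d: bad DEPS field '%s'", line_no, field))
  data.frame(head = head, dep = dep_id,
             label = sub("^[0-9]+:", "", parts), stringsAsFactors = FALSE)
}

check_acyclic_heads <- function(tokens) {
  head_of <- stats::setNames(tokens$head, tokens$id)
  for (start in tokens$id) {
    seen <- integer(); cur <- start
    while (!is.na(cur) && cur != 0L) {
      if (cur %in% seen)
        stop("cyclic HEAD chain in basic dependencies at token ", start)
      seen <- c(seen, cur)
      cur <- head_of[[as.character(cur)]]
      if (is.null(cur)) break
    }
  }
  invisible(TRUE)
}

#' Write sentences to CoNLL-U
#'
#' Inverse of [read_conllu()]: writing then re-reading round-trips tokens and
#' edges exactly. Sentences parsed from (or destined for) the enhanced
#' representation have their edges written to the DEPS column; basic HEAD is
#' then the enhanced head with the smallest id (or 0 for roots).
#'
#' @param sentences list of sentence records (see [read_conllu()]).
#' @param path output file path.
#' @export
write_conllu <- function(sentences, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (s in sentences) {
    for (k in names(s$meta))
      writeLines(sprintf("# %s = %s", k, s$meta[[k]]), con)
    tok <- s$tokens; deps <- s$deps
    for (r in seq_len(nrow(tok))) {
      id <- tok$id[r]
      mine <- deps[deps$dep == id, , drop = FALSE]
      if (nrow(mine)) {
        mine <- mine[order(mine$head), , drop = FALSE]
        basic_head <- mine$head[1L]
        basic_rel <- mine$label[1L]
      } else { basic_head <- 0L; basic_rel <- "root" }
      deps_field <- if (isTRUE(s$enhanced))
        paste(sprintf("%d:%s", mine$head, mine$label), collapse = "|") else "_"
      if (deps_field == "") deps_field <- "_"
      misc <- if (!is.null(tok$misc)) tok$misc[r] else "_"
      writeLines(paste(id, tok$form[r], tok$lemma[r], tok$upos[r], "_", "_",
                       basic_head, basic_rel, deps_field, misc, sep = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
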
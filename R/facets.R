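add_posting <- function(postings, facet, value, id) {
  if (is.null(postings[[facet]])) postings[[facet]] <- list()
  postings[[facet]][[value]] <- c(postings[[facet]][[value]], id)
  postings
}

#' Build a facet index over classified reports
#'
#' Turns annotations and incidence labels into searchable facets in one
#' append-only pass. Every report gets a `Presence` facet (`"true"` for a
#' positive label, `"false"` otherwise); reports with at least one condition
#' mention also get `Condition:<name>` — so negated mentions remain
#' retrievable under the Condition facet, with `Presence` carrying the
#' polarity. Any further annotation label (e.g. `Gender` from an analytics
#' dictionary) can be exposed as a facet via `facets`; its values are the
#' matched terms' canonical forms.
#'
#' @param docs List of `rad_doc` objects (as from
#'   `classify_corpus(..., keep_docs = TRUE)`; `NULL` entries, e.g. reports
#'   short-circuited by a title filter, are indexed from `labels` alone).
#' @param labels Label data frame aligned with `docs`.
#' @param facets Character vector of additional annotation labels to index.
#' @return A `facet_index`: postings (facet -> value -> sorted report ids)
#'   plus stored text and annotation spans for snippet rendering.
#' @export
build_index <- function(docs, labels, facets = character()) {
  postings <- list()
  stored <- list()
  for (i in seq_len(nrow(labels))) {
    id <- labels$report_id[i]
    if (!is.null(stored[[id]])) stop("duplicate report id: ", id)
    doc <- if (i <= length(docs)) docs[[i]] else NULL
    ann <- if (is.null(doc)) empty_annotations() else doc$annotations
    if (any(ann$label == "ConditionKeyword")) {
      postings <- add_posting(postings, "Condition", labels$condition[i], id)
    }
    postings <- add_posting(postings, "Presence",
                            if (labels$label[i] == "positive") "true" else "false",
                            id)
    for (f in facets) {
      rows <- which(ann$label == f)
      for (v in unique(sub("^dict:[^:]*:", "", ann$provenance[rows]))) {
        postings <- add_posting(postings, f, v, id)
      }
    }
    deciding <- if (!is.na(labels$deciding_start[i])) {
      c(labels$deciding_start[i], labels$deciding_end[i])
    }
    stored[[id]] <- list(
      text = if (is.null(doc)) "" else doc$text,
      title = if (is.null(doc)) NA_character_ else doc$title,
      annotations = ann, deciding = deciding)
  }
  for (f in names(postings)) {
    postings[[f]] <- lapply(postings[[f]], function(ids) sort(unique(ids)))
  }
  structure(list(version = 1L, postings = postings, stored = stored),
            class = "facet_index")
}

#' @export
print.facet_index <- function(x, ...) {
  cat(sprintf("<facet_index: %d reports, facets: %s>\n", length(x$stored),
              paste(names(x$postings), collapse = ", ")))
  invisible(x)
}

#' Search a facet index
#'
#' Facet predicates are conjunctive: the result is the sorted set of report
#' ids satisfying every `facet = value` pair and, if given, containing the
#' keyword as a (case-folded) token. An unknown facet or value yields an
#' empty result with a message, not an error.
#'
#' @param index A [build_index()] result.
#' @param facets Named character vector of predicates, e.g.
#'   `c(Condition = "hydronephrosis", Presence = "true")`.
#' @param keyword Optional single token to require in the report text.
#' @return Sorted character vector of report ids.
#' @export
search_index <- function(index, facets = NULL, keyword = NULL) {
  if ((is.null(facets) || length(facets) == 0L) && is.null(keyword)) {
    stop("query needs at least one facet predicate or a keyword")
  }
  ids <- NULL
  for (f in names(facets)) {
    p <- index$postings[[f]][[facets[[f]]]]
    if (is.null(p)) {
      message("no postings for facet ", f, "=", facets[[f]])
      p <- character()
    }
    ids <- if (is.null(ids)) p else intersect(ids, p)
  }
  if (!is.null(keyword)) {
    pool <- if (is.null(ids)) names(index$stored) else ids
    kw <- tolower(keyword)
    ids <- pool[vapply(pool, function(i) {
      kw %in% tolower(tokenize(index$stored[[i]]$text)$surface)
    }, logical(1))]
  }
  sort(unname(ids))
}

#' Render a highlighted snippet for a search hit
#'
#' Returns a window of text (+/- `window` tokens) around the deciding
#' mention — or the first annotation, or the report head when there is
#' neither — with non-overlapping annotation spans inside the window wrapped
#' in plain-text markup `[[label]]...[[/]]`, suitable for terminal or HTML
#' rendering.
#'
#' @param index A [build_index()] result.
#' @param report_id Report to render (unknown id is an error).
#' @param window Tokens of context either side of the anchor. Default 10.
#' @return A character string.
#' @export
render_snippet <- function(index, report_id, window = 10L) {
  entry <- index$stored[[report_id]]
  if (is.null(entry)) stop("unknown report id: ", report_id)
  toks <- tokenize(entry$text)
  n <- nrow(toks)
  if (n == 0L) return("")
  ann <- entry$annotations
  anchor <- if (!is.null(entry$deciding)) {
    entry$deciding
  } else if (nrow(ann) > 0L) {
    c(ann$start[1L], ann$end[1L])
  }
  if (is.null(anchor)) {
    w0 <- 1L
    w1 <- min(n, 2L * window + 1L)
  } else {
    at <- which(toks$start < anchor[2L] & toks$end > anchor[1L])
    w0 <- max(1L, min(at) - window)
    w1 <- min(n, max(at) + window)
  }
  cs <- toks$start[w0]
  ce <- toks$end[w1]
  hl <- ann[ann$start >= cs & ann$end <= ce, , drop = FALSE]
  hl <- hl[order(hl$start, -hl$end), , drop = FALSE]
  # keep non-overlapping highlights in offset order
  keep <- logical(nrow(hl))
  last_end <- -1L
  for (i in seq_len(nrow(hl))) {
    if (hl$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- hl$end[i]
    }
  }
  hl <- hl[keep, , drop = FALSE]
  out <- ""
  pos <- cs
  for (i in seq_len(nrow(hl))) {
    out <- paste0(out, substr(entry$text, pos + 1L, hl$start[i]),
                  "[[", hl$label[i], "]]",
                  substr(entry$text, hl$start[i] + 1L, hl$end[i]), "[[/]]")
    pos <- hl$end[i]
  }
  paste0(out, substr(entry$text, pos + 1L, ce))
}

#' Persist / load a facet index
#'
#' The index is stored as a single portable JSON file with a versioned
#' header; [read_facet_index()] reconstructs the in-memory structure.
#'
#' @param index A `facet_index`.
#' @param path Output file.
#' @return `path` (write) or the reconstructed `facet_index` (read).
#' @export
write_facet_index <- function(index, path) {
  ser <- list(
    version = index$version,
    postings = index$postings,
    stored = lapply(index$stored, function(e) {
      list(text = e$text, title = e$title, deciding = e$deciding,
           annotations = as.list(e$annotations))
    })
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_facet_index
#' @export
read_facet_index <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  postings <- lapply(raw$postings, function(vals) {
    lapply(vals, function(ids) as.character(unlist(ids)))
  })
  stored <- lapply(raw$stored, function(e) {
    cols <- lapply(e$annotations, unlist)
    ann <- if (length(cols) == 0L || length(cols$label) == 0L) {
      empty_annotations()
    } else {
      data.frame(label = as.character(cols$label),
                 start = as.integer(cols$start),
                 end = as.integer(cols$end),
                 sentence = as.integer(cols$sentence),
                 token_start = as.integer(cols$token_start),
                 token_end = as.integer(cols$token_end),
                 present = as.character(cols$present),
                 polarity = as.character(cols$polarity),
                 last_occurrence = as.character(cols$last_occurrence),
                 provenance = as.character(cols$provenance),
                 stringsAsFactors = FALSE)
    }
    list(text = e$text %||% "",
         title = if (is.null(e$title)) NA_character_ else e$title,
         annotations = ann,
         deciding = if (length(e$deciding)) as.integer(unlist(e$deciding)))
  })
  structure(list(version = raw$version, postings = postings, stored = stored),
            class = "facet_index")
}
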
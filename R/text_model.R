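#' Tokenize report text
#'
#' Rule-based scanner: maximal runs of letters/digits form word tokens
#' (hyphenated words are kept whole), every other non-space character is a
#' single-character token. Character offsets are 0-based, half-open, so
#' `substr(text, start + 1, end)` recovers each surface form exactly.
#'
#' @param text A single character string (may be empty).
#' @return A data frame with columns `surface`, `start`, `end`, one row per
#'   token, sorted by `start` and non-overlapping.
#' @examples
#' tokenize("IMPRESSION: No definite hydronephrosis.")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) text <- ""
  empty <- data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  m <- gregexpr("[[:alnum:]]+(?:-[[:alnum:]]+)*|[^[:alnum:][:space:]]",
                text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  len <- attr(m, "match.length")
  data.frame(
    surface = substring(text, m, m + len - 1L),
    start = as.integer(m - 1L),
    end = as.integer(m - 1L + len),
    stringsAsFactors = FALSE
  )
}

# Section header keywords (followed by ":") and their mapped section labels.
.header_map <- c(
  reason = "REASON", indication = "REASON",
  history = "HISTORY",
  findings = "FINDINGS",
  impression = "IMPRESSION", conclusion = "IMPRESSION"
)

# If tokens[i] opens a section header ("FINDINGS :", "CLINICAL HISTORY :"),
# return list(label, len); otherwise NULL. `low` is tolower(surface).
header_at <- function(low, i) {
  n <- length(low)
  if (low[i] == "clinical" && i + 2L <= n &&
      low[i + 1L] == "history" && low[i + 2L] == ":") {
    return(list(label = "HISTORY", len = 2L))
  }
  lab <- .header_map[low[i]]
  if (!is.na(lab) && i + 1L <= n && low[i + 1L] == ":") {
    return(list(label = unname(lab), len = 1L))
  }
  NULL
}

#' Segment tokens into sentences
#'
#' Sentence boundaries fall after terminal punctuation (`.`, `!`, `?`), at any
#' newline run between tokens, and before a recognized section header keyword
#' followed by `:`. Semicolons and ordinary colons never split, so one-line
#' header strings such as `"Reason: Evaluate for effusion; Admitting
#' Diagnosis: HYDRONEPHROSIS"` remain a single scope.
#'
#' @param tokens Token data frame from [tokenize()].
#' @param text The text the tokens were produced from.
#' @return A data frame with one row per sentence: `index` (0-based),
#'   `token_start`/`token_end` (1-based inclusive row indices into `tokens`),
#'   and character offsets `start`/`end`.
#' @export
segment_sentences <- function(tokens, text) {
  n <- nrow(tokens)
  empty <- data.frame(index = integer(), token_start = integer(),
                      token_end = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  low <- tolower(tokens$surface)
  brk <- logical(n)
  brk[1L] <- TRUE
  if (n > 1L) {
    for (i in 2:n) {
      gap <- if (tokens$start[i] > tokens$end[i - 1L]) {
        substr(text, tokens$end[i - 1L] + 1L, tokens$start[i])
      } else ""
      # a two-word "CLINICAL HISTORY:" header breaks before "clinical" only
      header_here <- !is.null(header_at(low, i)) &&
        !(low[i] == "history" && low[i - 1L] == "clinical")
      brk[i] <- tokens$surface[i - 1L] %in% c(".", "!", "?") ||
        grepl("\n", gap, fixed = TRUE) ||
        header_here
    }
  }
  first <- which(brk)
  last <- c(first[-1L] - 1L, n)
  data.frame(
    index = seq_along(first) - 1L,
    token_start = first, token_end = last,
    start = tokens$start[first], end = tokens$end[last],
    stringsAsFactors = FALSE
  )
}

#' Detect report sections
#'
#' A sentence whose first tokens are a header keyword (REASON, INDICATION,
#' HISTORY, CLINICAL HISTORY, FINDINGS, IMPRESSION, CONCLUSION,
#' case-insensitive) followed by `:` opens a section with the mapped label
#' (INDICATION maps to REASON, CONCLUSION to IMPRESSION). Leading unheaded
#' sentences form an OTHER section. Sections partition the sentences.
#'
#' @param sentences Sentence data frame from [segment_sentences()].
#' @param tokens Token data frame from [tokenize()].
#' @return A data frame with columns `label`, `sent_start`, `sent_end`
#'   (1-based inclusive row indices into `sentences`).
#' @export
detect_sections <- function(sentences, tokens) {
  empty <- data.frame(label = character(), sent_start = integer(),
                      sent_end = integer(), stringsAsFactors = FALSE)
  ns <- nrow(sentences)
  if (ns == 0L) return(empty)
  low <- tolower(tokens$surface)
  labs <- vapply(seq_len(ns), function(i) {
    h <- header_at(low, sentences$token_start[i])
    if (is.null(h)) NA_character_ else h$label
  }, character(1))
  heads <- which(!is.na(labs))
  if (length(heads) == 0L) {
    return(data.frame(label = "OTHER", sent_start = 1L, sent_end = ns,
                      stringsAsFactors = FALSE))
  }
  out <- list()
  if (heads[1L] > 1L) {
    out[[length(out) + 1L]] <- data.frame(label = "OTHER", sent_start = 1L,
                                          sent_end = heads[1L] - 1L,
                                          stringsAsFactors = FALSE)
  }
  bounds <- c(heads, ns + 1L)
  for (k in seq_along(heads)) {
    out[[length(out) + 1L]] <- data.frame(
      label = labs[heads[k]], sent_start = heads[k],
      sent_end = bounds[k + 1L] - 1L, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Coerce a one-row data frame or a list to the internal report structure.
as_report <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- as.list(x)
  }
  list(
    id = as.character(x$id %||% stop("report must have an 'id'")),
    title = if (is.null(x$title)) NA_character_ else as.character(x$title),
    text = as.character(x$text %||% ""),
    locale = as.character(x$locale %||% "unknown")
  )
}

#' Tokenize, segment, and annotate a single report
#'
#' Runs the shallow document analysis (tokens, sentences, sections) and
#' matches each supplied dictionary, producing one annotation per maximal
#' in-sentence term match.
#'
#' @param report A list or one-row data frame with fields `id`, `text`, and
#'   optional `title`, `locale`.
#' @param dictionaries A (possibly empty) list of [rad_dictionary()] objects.
#' @return A `rad_doc` object: list with `id`, `title`, `text`, `locale`,
#'   `tokens`, `sentences`, `sections`, `tok_sentence` (0-based sentence index
#'   per token), `annotations`, and `labels` (the annotation-label inventory).
#' @export
annotate_report <- function(report, dictionaries = list()) {
  report <- as_report(report)
  toks <- tokenize(report$text)
  sents <- segment_sentences(toks, report$text)
  secs <- detect_sections(sents, toks)
  tok_sent <- integer(nrow(toks))
  for (i in seq_len(nrow(sents))) {
    tok_sent[sents$token_start[i]:sents$token_end[i]] <- sents$index[i]
  }
  doc <- structure(
    list(id = report$id, title = report$title, text = report$text,
         locale = report$locale, tokens = toks, sentences = sents,
         sections = secs, tok_sentence = tok_sent,
         annotations = empty_annotations(), labels = character()),
    class = "rad_doc"
  )
  for (d in dictionaries) {
    doc$annotations <- rbind(doc$annotations, match_terms(doc, d))
    doc$labels <- union(doc$labels, d$name)
  }
  doc$annotations <- sort_annotations(doc$annotations)
  doc
}

#' @export
print.rad_doc <- function(x, ...) {
  cat(sprintf("<rad_doc %s: %d chars, %d tokens, %d sentences, %d annotations>\n",
              x$id, nchar(x$text), nrow(x$tokens), nrow(x$sentences),
              nrow(x$annotations)))
  invisible(x)
}
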
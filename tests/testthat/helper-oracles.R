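# Independent brute-force oracles. These deliberately re-derive the expected
# behaviour with naive algorithms (exhaustive window scans, permutation
# checks, linear scans) so the package implementation is checked against a
# second, structurally different route.

# Dictionary matcher oracle: test every (start, length) window of every
# sentence against every term, then drop windows strictly contained in a
# longer hit.
oracle_match <- function(doc, dict) {
  norm <- normalize_tokens(doc$tokens$surface, dict$case_fold, dict$locale_map)
  hits <- list()
  for (s in seq_len(nrow(doc$sentences))) {
    a <- doc$sentences$token_start[s]
    b <- doc$sentences$token_end[s]
    for (i in a:b) {
      for (j in i:b) {
        win <- norm[i:j]
        for (ph in dict$phrases) {
          if (length(ph) == length(win) && all(ph == win)) {
            hits[[length(hits) + 1L]] <- c(i, j)
          }
        }
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(token_start = integer(), token_end = integer()))
  }
  h <- unique(do.call(rbind, hits))
  keep <- vapply(seq_len(nrow(h)), function(i) {
    !any(h[, 1L] <= h[i, 1L] & h[, 2L] >= h[i, 2L] &
           (h[, 2L] - h[, 1L]) > (h[i, 2L] - h[i, 1L]))
  }, logical(1))
  h <- h[keep, , drop = FALSE]
  h <- h[order(h[, 1L], h[, 2L]), , drop = FALSE]
  data.frame(token_start = h[, 1L], token_end = h[, 2L])
}

# All permutations of 1..n (n small).
perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms(n - 1L)) {
    for (k in 0:(n - 1L)) out[[length(out) + 1L]] <- append(p, n, after = k)
  }
  out
}

# Sentence-scope rule oracle. Enumerates every tuple of distinct instances
# (one per element, same sentence) by recursive descent and checks the
# order/gap constraints positionally: for ordered rules the declared order
# must hold; for unordered rules some permutation must satisfy the ordered
# constraints. Returns, for create actions, the unique matched extents
# (token_start, token_end); for set actions, the annotation row indices of
# the target element across satisfying tuples.
oracle_sentence_rule <- function(rule, doc) {
  inst <- lapply(rule$elements, function(el) {
    if (el$type == "annotation") {
      idx <- which(doc$annotations$label == el$label)
      data.frame(ts = doc$annotations$token_start[idx],
                 te = doc$annotations$token_end[idx], ann = idx,
                 sent = doc$annotations$sentence[idx])
    } else {
      idx <- which(tolower(doc$tokens$surface) == el$literal)
      data.frame(ts = idx, te = idx, ann = NA_integer_,
                 sent = doc$tok_sentence[idx])
    }
  })
  m <- length(inst)
  satisfies_ordered <- function(ts, te) {
    if (m == 1L) return(TRUE)
    all(ts[-1L] - te[-m] - 1 >= 0) && all(ts[-1L] - te[-m] - 1 <= rule$max_gap)
  }
  results <- list()
  tuples <- function(chosen, depth) {
    if (depth > m) {
      ts <- vapply(chosen, `[[`, numeric(1), "ts")
      te <- vapply(chosen, `[[`, numeric(1), "te")
      ok <- if (rule$ordered) {
        satisfies_ordered(ts, te)
      } else {
        any(vapply(perms(m), function(p) satisfies_ordered(ts[p], te[p]),
                   logical(1)))
      }
      if (ok) results[[length(results) + 1L]] <<- chosen
      return(invisible())
    }
    d <- inst[[depth]]
    for (r in seq_len(nrow(d))) {
      cand <- d[r, ]
      dup <- any(vapply(chosen, function(c0) {
        (!is.na(c0$ann) && !is.na(cand$ann) && c0$ann == cand$ann) ||
          (is.na(c0$ann) && is.na(cand$ann) && c0$ts == cand$ts)
      }, logical(1)))
      same_sent <- all(vapply(chosen, function(c0) c0$sent == cand$sent,
                              logical(1)))
      if (!dup && same_sent) tuples(c(chosen, list(cand)), depth + 1L)
    }
  }
  tuples(list(), 1L)
  if (rule$action$type == "create") {
    if (length(results) == 0L) {
      return(data.frame(token_start = integer(), token_end = integer()))
    }
    ext <- unique(do.call(rbind, lapply(results, function(ch) {
      ts <- vapply(ch, `[[`, numeric(1), "ts")
      te <- vapply(ch, `[[`, numeric(1), "te")
      c(min(ts), max(te))
    })))
    ext <- ext[order(ext[, 1L], ext[, 2L]), , drop = FALSE]
    data.frame(token_start = as.integer(ext[, 1L]),
               token_end = as.integer(ext[, 2L]))
  } else {
    sort(unique(vapply(results, function(ch) ch[[rule$action$target]]$ann,
                       numeric(1))))
  }
}

# Facet search oracle: linear scan over stored reports.
oracle_search <- function(docs, labels, facets = NULL, keyword = NULL) {
  hit <- rep(TRUE, nrow(labels))
  for (f in names(facets)) {
    v <- facets[[f]]
    hit <- hit & vapply(seq_len(nrow(labels)), function(i) {
      doc <- docs[[labels$report_id[i]]]
      ann <- if (is.null(doc)) empty_ann_df() else doc$annotations
      if (f == "Condition") {
        any(ann$label == "ConditionKeyword") && labels$condition[i] == v
      } else if (f == "Presence") {
        (labels$label[i] == "positive") == (v == "true")
      } else {
        any(ann$label == f & sub("^dict:[^:]*:", "", ann$provenance) == v)
      }
    }, logical(1))
  }
  if (!is.null(keyword)) {
    hit <- hit & vapply(seq_len(nrow(labels)), function(i) {
      doc <- docs[[labels$report_id[i]]]
      !is.null(doc) && tolower(keyword) %in% tolower(tokenize(doc$text)$surface)
    }, logical(1))
  }
  sort(labels$report_id[hit])
}

empty_ann_df <- function() {
  data.frame(label = character(), provenance = character(),
             stringsAsFactors = FALSE)
}

# Confusion-matrix recount oracle.
oracle_counts <- function(predictions, gold) {
  g <- gold$gold_label[match(predictions$report_id, gold$report_id)]
  tab <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (i in seq_along(g)) {
    p <- predictions$label[i]
    tab[[if (p == "positive" && g[i] == "positive") "TP"
         else if (p == "positive") "FP"
         else if (g[i] == "positive") "FN" else "TN"]] <-
      tab[[if (p == "positive" && g[i] == "positive") "TP"
           else if (p == "positive") "FP"
           else if (g[i] == "positive") "FN" else "TN"]] + 1L
  }
  tab
}
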
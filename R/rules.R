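#' Rule pattern elements
#'
#' Building blocks for [rule_spec()]: a rule element matches either every
#' annotation with a given label, or every token whose case-folded surface
#' equals a literal.
#'
#' @param label Annotation label to match.
#' @return A `rule_element`.
#' @export
ann_pattern <- function(label) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  structure(list(type = "annotation", label = label), class = "rule_element")
}

#' @rdname ann_pattern
#' @param literal Token surface literal (case-insensitive).
#' @export
token_pattern <- function(literal) {
  stopifnot(is.character(literal), length(literal) == 1L, nzchar(literal))
  structure(list(type = "token", literal = tolower(literal)),
            class = "rule_element")
}

#' Rule actions
#'
#' `action_create()` creates a new annotation over the matched extent;
#' `action_set()` sets a feature on the annotation matched by one of the
#' rule's elements (a feature is only written while still `"unknown"`, so the
#' first rule to set it wins); `action_mark_last()` marks the last occurrence
#' of a label in the document (see [mark_last_occurrence()]).
#'
#' @param label Label of the created / marked annotation.
#' @param features Named list of initial feature values for the created
#'   annotation (keys among `present`, `polarity`, `last_occurrence`).
#' @return An action list understood by [apply_rule()].
#' @export
action_create <- function(label, features = list()) {
  list(type = "create", label = label, features = features)
}

#' @rdname action_create
#' @param target 1-based index of the rule element whose annotation receives
#'   the feature; must be an annotation element.
#' @param key Feature key: `"present"`, `"polarity"`, or `"last_occurrence"`.
#' @param value Feature value to set.
#' @export
action_set <- function(target, key, value) {
  stopifnot(key %in% c("present", "polarity", "last_occurrence"))
  list(type = "set", target = as.integer(target), key = key, value = value)
}

#' @rdname action_create
#' @export
action_mark_last <- function(label) {
  list(type = "mark_last", label = label)
}

#' Declare a pattern rule over tokens and annotations
#'
#' A rule fires once for every combination of element instances inside one
#' scope unit that satisfies the order and gap constraints. In an ordered
#' group, elements must occur in declared order without overlapping; in an
#' unordered (disordered) group they may occur in any order. `max_gap` bounds
#' the number of tokens between the closest edges of consecutive matched
#' elements (after sorting by position for unordered groups).
#'
#' @param id Unique rule id within a rule set.
#' @param elements List of [ann_pattern()] / [token_pattern()] elements (may
#'   be empty only for an [action_mark_last()] rule).
#' @param action An action from [action_create()], [action_set()], or
#'   [action_mark_last()].
#' @param scope `"sentence"`, `"document"`, or an integer `k` for a k-token
#'   window (all elements within `k` consecutive tokens).
#' @param ordered Must elements appear in declared order? Default `TRUE`.
#' @param max_gap Maximum tokens between consecutive elements; `Inf` (the
#'   default) leaves the gap unbounded within the scope.
#' @return A `rule_spec`.
#' @examples
#' # "a body organ and a cancer keyword with at most five tokens in between"
#' rule_spec("cancer-location",
#'   elements = list(ann_pattern("BodyOrgan"), ann_pattern("Cancer")),
#'   action = action_create("CancerLocation"),
#'   scope = "sentence", ordered = FALSE, max_gap = 5)
#' @export
rule_spec <- function(id, elements, action, scope = "sentence",
                      ordered = TRUE, max_gap = Inf) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.numeric(scope)) {
    stopifnot(scope >= 1)
    scope <- list(type = "window", k = as.integer(scope))
  } else {
    scope <- match.arg(scope, c("sentence", "document"))
    scope <- list(type = scope)
  }
  stopifnot(is.list(elements), is.numeric(max_gap), max_gap >= 0)
  if (action$type != "mark_last" && length(elements) == 0L) {
    stop("rule '", id, "': at least one element is required")
  }
  for (el in elements) {
    if (!inherits(el, "rule_element")) {
      stop("rule '", id, "': elements must be ann_pattern()/token_pattern()")
    }
  }
  if (action$type == "set") {
    if (action$target < 1L || action$target > length(elements)) {
      stop("rule '", id, "': set-feature target out of range")
    }
    if (elements[[action$target]]$type != "annotation") {
      stop("rule '", id, "': set-feature target must be an annotation element")
    }
  }
  structure(
    list(id = id, scope = scope, elements = elements, ordered = ordered,
         max_gap = max_gap, action = action),
    class = "rule_spec"
  )
}

#' Combine rules into an ordered rule set
#'
#' Rules are applied in declared order; because a feature is only written
#' while `"unknown"`, earlier rules take precedence for the same target
#' feature.
#'
#' @param name Rule-set name.
#' @param rules List of [rule_spec()] objects with unique ids.
#' @return A `rule_set`.
#' @export
rule_set <- function(name, rules) {
  ids <- vapply(rules, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate rule id(s): ", paste(unique(ids[duplicated(ids)]),
                                         collapse = ", "))
  }
  structure(list(name = name, rules = rules), class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set %s: %d rules>\n", x$name, length(x$rules)))
  for (r in x$rules) cat("  -", r$id, "\n")
  invisible(x)
}

# All instances of one rule element in a document: data frame with token
# range (ts, te), annotation row index (NA for token literals), sentence.
element_instances <- function(el, doc) {
  if (el$type == "annotation") {
    idx <- which(doc$annotations$label == el$label)
    data.frame(ts = doc$annotations$token_start[idx],
               te = doc$annotations$token_end[idx],
               ann = idx, sent = doc$annotations$sentence[idx])
  } else {
    idx <- which(tolower(doc$tokens$surface) == el$literal)
    data.frame(ts = idx, te = idx, ann = rep(NA_integer_, length(idx)),
               sent = doc$tok_sentence[idx])
  }
}

#' Apply a single rule to an annotated document
#'
#' Enumerates element-instance combinations per scope unit, checks order and
#' gap constraints, and fires the rule's action once per satisfying
#' combination. Created annotations are de-duplicated on (label, span);
#' set-feature writes only features currently `"unknown"`. The created or
#' marked label is registered in the document's label inventory even when the
#' rule fires zero times; a set-feature rule whose target label is not in the
#' inventory is an error.
#'
#' @param rule A [rule_spec()].
#' @param doc A `rad_doc` with dictionary annotations already matched.
#' @return The updated `rad_doc`.
#' @export
apply_rule <- function(rule, doc) {
  act <- rule$action
  if (act$type == "create") doc$labels <- union(doc$labels, act$label)
  if (act$type == "mark_last") {
    doc$labels <- union(doc$labels, act$label)
    doc$annotations <- mark_last_occurrence(doc$annotations, act$label)
    return(doc)
  }
  if (act$type == "set") {
    tl <- rule$elements[[act$target]]$label
    if (!tl %in% doc$labels) {
      stop("rule '", rule$id, "': set-feature target label '", tl,
           "' is not in the annotation inventory")
    }
  }
  inst <- lapply(rule$elements, element_instances, doc = doc)
  if (any(vapply(inst, nrow, integer(1)) == 0L)) return(doc)

  units <- if (rule$scope$type == "sentence") {
    sort(unique(doc$sentences$index))
  } else {
    NA_integer_  # document / window: one unit
  }
  created <- list()
  for (u in units) {
    sub <- if (is.na(u)) inst else lapply(inst, function(d) d[d$sent == u, , drop = FALSE])
    if (any(vapply(sub, nrow, integer(1)) == 0L)) next
    combos <- expand.grid(lapply(sub, function(d) seq_len(nrow(d))),
                          KEEP.OUT.ATTRS = FALSE)
    for (ci in seq_len(nrow(combos))) {
      pick <- lapply(seq_along(sub), function(j) sub[[j]][combos[ci, j], ])
      ts <- vapply(pick, `[[`, numeric(1), "ts")
      te <- vapply(pick, `[[`, numeric(1), "te")
      ann <- vapply(pick, `[[`, numeric(1), "ann")
      # distinct instances: no shared annotation row or token position
      key <- paste(ifelse(is.na(ann), paste0("t", ts), paste0("a", ann)))
      if (anyDuplicated(key)) next
      if (rule$ordered) {
        o <- seq_along(ts)
      } else {
        o <- order(ts)
      }
      ok <- TRUE
      if (length(ts) > 1L) {
        for (j in 2:length(o)) {
          gap <- ts[o[j]] - te[o[j - 1L]] - 1
          if (gap < 0 || gap > rule$max_gap) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      if (rule$scope$type == "window" &&
          (max(te) - min(ts) + 1) > rule$scope$k) next
      if (act$type == "create") {
        created[[length(created) + 1L]] <- c(min(ts), max(te))
      } else {
        tgt <- ann[act$target]
        if (doc$annotations[[act$key]][tgt] == "unknown") {
          doc$annotations[[act$key]][tgt] <- act$value
        }
      }
    }
  }
  if (act$type == "create" && length(created) > 0L) {
    m <- unique(do.call(rbind, created))
    feats <- act$features
    rows <- new_annotations(
      label = act$label,
      start = doc$tokens$start[m[, 1L]], end = doc$tokens$end[m[, 2L]],
      sentence = doc$tok_sentence[m[, 1L]],
      token_start = m[, 1L], token_end = m[, 2L],
      present = feats$present %||% "unknown",
      polarity = feats$polarity %||% "unknown",
      last_occurrence = feats$last_occurrence %||% "unknown",
      provenance = paste0("rule:", rule$id)
    )
    # drop creations identical to an existing annotation (idempotence)
    exist <- paste(doc$annotations$label, doc$annotations$start,
                   doc$annotations$end)
    rows <- rows[!paste(rows$label, rows$start, rows$end) %in% exist, ,
                 drop = FALSE]
    doc$annotations <- sort_annotations(rbind(doc$annotations, rows))
  }
  doc
}

#' Apply a rule set to an annotated document
#'
#' Rules run in declared order; the result is deterministic and annotations
#' come back sorted by (start, label).
#'
#' @param rs A [rule_set()].
#' @param doc A `rad_doc` with dictionaries already matched.
#' @return The updated `rad_doc`.
#' @export
apply_ruleset <- function(rs, doc) {
  for (r in rs$rules) doc <- apply_rule(r, doc)
  doc$annotations <- sort_annotations(doc$annotations)
  doc
}

#' Mark the last occurrence of a label
#'
#' Among annotations with the given label, exactly the one with maximal start
#' offset gets `last_occurrence = "true"`; the others get `"false"`. Useful
#' when the final condition mention in a report (typically the impression)
#' should decide the document label, suppressing earlier historical or
#' hedged mentions.
#'
#' @param annotations An annotation data frame.
#' @param label Label whose occurrences are marked.
#' @return The updated annotation data frame (unchanged if no occurrences).
#' @export
mark_last_occurrence <- function(annotations, label) {
  idx <- which(annotations$label == label)
  if (length(idx) == 0L) return(annotations)
  annotations$last_occurrence[idx] <- "false"
  annotations$last_occurrence[idx[which.max(annotations$start[idx])]] <- "true"
  annotations
}
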
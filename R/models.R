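#' Define a condition model
#'
#' A condition model bundles everything needed to decide whether a report is
#' a positive incidence of a condition: how condition mentions are found
#' (`cohesive` — one keyword dictionary whose terms occur contiguously, as
#' for hydronephrosis; or `paired` — two dictionaries whose members must
#' co-occur within one sentence, as for brain metastasis where brain-related
#' and metastasis-indicating words are non-contiguous), which
#' negative-instance indicator dictionaries flip a mention to not-present,
#' and the optional last-occurrence and title-filter heuristics.
#'
#' @param condition Condition name (e.g. `"hydronephrosis"`).
#' @param keyword_mode `"cohesive"` or `"paired"`.
#' @param condition_dict Dictionary role holding the condition keywords
#'   (cohesive mode).
#' @param dict1,dict2 Dictionary roles for the paired mode (e.g. brain-related
#'   and metastasis-indicating keywords).
#' @param paired_max_gap Maximum tokens between the two paired keywords;
#'   default `Inf` (whole sentence).
#' @param negative_dicts Non-empty character vector of indicator dictionary
#'   roles applied as sentence-scoped pre-keyword rules.
#' @param use_ordered_post_indicator Also apply indicator-after-keyword rules?
#'   Default `FALSE`.
#' @param use_last_occurrence Decide the document label from the last
#'   condition mention only? Default `TRUE`.
#' @param recall_over_precision Disable the negation rule so hedged negations
#'   ("without frank ...") count as positive, for recall-oriented
#'   quality-assurance use. Default `FALSE`.
#' @param title_filter Optional character vector of title keywords; when set,
#'   a report whose title contains none of them is classified negative
#'   without rule application (reports without a title always pass).
#' @return A `condition_model`.
#' @export
condition_model <- function(condition,
                            keyword_mode = c("cohesive", "paired"),
                            condition_dict = NULL,
                            dict1 = NULL, dict2 = NULL,
                            paired_max_gap = Inf,
                            negative_dicts = c("NegationIndicator",
                                               "EvaluationIndicator",
                                               "HistoryIndicator",
                                               "ResolutionIndicator"),
                            use_ordered_post_indicator = FALSE,
                            use_last_occurrence = TRUE,
                            recall_over_precision = FALSE,
                            title_filter = NULL) {
  keyword_mode <- match.arg(keyword_mode)
  if (length(negative_dicts) == 0L) {
    stop("negative_dicts must name at least one indicator dictionary")
  }
  if (keyword_mode == "cohesive" && is.null(condition_dict)) {
    stop("cohesive mode requires 'condition_dict'")
  }
  if (keyword_mode == "paired" && (is.null(dict1) || is.null(dict2))) {
    stop("paired mode requires both 'dict1' and 'dict2'")
  }
  structure(
    list(condition = condition, keyword_mode = keyword_mode,
         condition_dict = condition_dict, dict1 = dict1, dict2 = dict2,
         paired_max_gap = paired_max_gap, negative_dicts = negative_dicts,
         use_ordered_post_indicator = use_ordered_post_indicator,
         use_last_occurrence = use_last_occurrence,
         recall_over_precision = recall_over_precision,
         title_filter = title_filter),
    class = "condition_model"
  )
}

#' @export
print.condition_model <- function(x, ...) {
  cat(sprintf("<condition_model %s: %s mode, %d indicator dicts%s%s>\n",
              x$condition, x$keyword_mode, length(x$negative_dicts),
              if (x$use_last_occurrence) ", last-occurrence" else "",
              if (x$recall_over_precision) ", recall-over-precision" else ""))
  invisible(x)
}

# Dictionary roles the model needs matched before its rule set runs.
required_roles <- function(model) {
  kw <- if (model$keyword_mode == "cohesive") model$condition_dict else
    c(model$dict1, model$dict2)
  c(kw, model$negative_dicts)
}

#' Build the rule set of a condition model
#'
#' Emits, in order: (a) the ConditionKeyword creation rule (single-dictionary
#' in cohesive mode; sentence-level unordered co-occurrence of the two
#' dictionaries in paired mode); (b) for each indicator dictionary `D`, the
#' sentence-scoped ordered rule "`D` then ConditionKeyword sets present =
#' false"; (c) optionally the post-positioned variant "ConditionKeyword then
#' `D`"; (d) the default rule setting present = true on any mention still
#' unknown; (e) optionally the last-occurrence marking step. With the four
#' standard indicator dictionaries and default flags this yields 7 rules.
#'
#' @param model A [condition_model()].
#' @param dictionaries Named list of loaded [rad_dictionary()] objects; every
#'   role the model references must be present.
#' @return A [rule_set()].
#' @export
build_condition_ruleset <- function(model, dictionaries) {
  missing <- setdiff(required_roles(model), names(dictionaries))
  if (length(missing) > 0L) {
    stop("missing dictionary: ", paste(missing, collapse = ", "))
  }
  rules <- list()
  init <- list(present = "unknown", polarity = "unknown")
  if (model$keyword_mode == "cohesive") {
    rules[[1L]] <- rule_spec(
      "condition-keyword",
      elements = list(ann_pattern(model$condition_dict)),
      action = action_create("ConditionKeyword", init),
      scope = "sentence")
  } else {
    rules[[1L]] <- rule_spec(
      "condition-keyword-paired",
      elements = list(ann_pattern(model$dict1), ann_pattern(model$dict2)),
      action = action_create("ConditionKeyword", init),
      scope = "sentence", ordered = FALSE, max_gap = model$paired_max_gap)
  }
  negs <- model$negative_dicts
  if (model$recall_over_precision) negs <- setdiff(negs, "NegationIndicator")
  for (d in negs) {
    rules[[length(rules) + 1L]] <- rule_spec(
      paste0("pre-", d),
      elements = list(ann_pattern(d), ann_pattern("ConditionKeyword")),
      action = action_set(2L, "present", "false"),
      scope = "sentence", ordered = TRUE)
  }
  if (model$use_ordered_post_indicator) {
    for (d in negs) {
      rules[[length(rules) + 1L]] <- rule_spec(
        paste0("post-", d),
        elements = list(ann_pattern("ConditionKeyword"), ann_pattern(d)),
        action = action_set(1L, "present", "false"),
        scope = "sentence", ordered = TRUE)
    }
  }
  rules[[length(rules) + 1L]] <- rule_spec(
    "default-positive",
    elements = list(ann_pattern("ConditionKeyword")),
    action = action_set(1L, "present", "true"),
    scope = "sentence")
  if (model$use_last_occurrence) {
    rules[[length(rules) + 1L]] <- rule_spec(
      "last-occurrence", elements = list(),
      action = action_mark_last("ConditionKeyword"))
  }
  rule_set(model$condition, rules)
}

#' Does the model apply to this report's title?
#'
#' `TRUE` when the model has no title filter, the report has no title, or the
#' (case-folded, tokenized) title contains any filter keyword. A title of
#' "CT Head" passes a `{head, brain}` filter; "CT Abdomen" does not.
#'
#' @param report Report list or one-row data frame.
#' @param model A [condition_model()].
#' @return Logical scalar.
#' @export
apply_title_filter <- function(report, model) {
  if (is.null(model$title_filter) || length(model$title_filter) == 0L) {
    return(TRUE)
  }
  report <- as_report(report)
  title <- report$title
  if (is.na(title) || !nzchar(title)) return(TRUE)
  any(tolower(model$title_filter) %in% tolower(tokenize(title)$surface))
}

incidence_row <- function(id, condition, label,
                          deciding_start = NA_integer_,
                          deciding_end = NA_integer_, n_mentions = 0L) {
  data.frame(report_id = id, condition = condition, label = label,
             deciding_start = as.integer(deciding_start),
             deciding_end = as.integer(deciding_end),
             n_mentions = as.integer(n_mentions), stringsAsFactors = FALSE)
}

#' Classify one report as positive or negative incidence
#'
#' Runs the full per-document pipeline: title filter, tokenization and
#' sentence segmentation, dictionary matching, rule application, and the
#' document decision. With `use_last_occurrence` on, the label is positive
#' iff the last condition mention has `present = "true"`; otherwise iff any
#' mention does. A report without condition mentions is negative.
#'
#' @param report Report list or one-row data frame (`id`, `text`, optional
#'   `title`, `locale`).
#' @param model A [condition_model()].
#' @param dictionaries Named list of [rad_dictionary()] objects covering the
#'   model's roles.
#' @param return_doc Also return the annotated document? Default `FALSE`.
#' @return A one-row data frame (`report_id`, `condition`, `label`,
#'   `deciding_start`, `deciding_end`, `n_mentions`), or, with
#'   `return_doc = TRUE`, a list with components `label` and `doc`.
#' @examples
#' m <- builtin_condition_model("hydronephrosis")
#' d <- builtin_dictionaries(m)
#' classify_report(list(id = "r1", text = "Moderate hydronephrosis is noted."),
#'                 m, d)$label
#' @export
classify_report <- function(report, model, dictionaries, return_doc = FALSE) {
  report <- as_report(report)
  if (!apply_title_filter(report, model)) {
    lab <- incidence_row(report$id, model$condition, "negative")
    return(if (return_doc) list(label = lab, doc = NULL) else lab)
  }
  doc <- annotate_report(report, dictionaries[required_roles(model)])
  rs <- build_condition_ruleset(model, dictionaries)
  doc <- apply_ruleset(rs, doc)
  ck <- doc$annotations[doc$annotations$label == "ConditionKeyword", ,
                        drop = FALSE]
  if (nrow(ck) == 0L) {
    lab <- incidence_row(report$id, model$condition, "negative")
  } else if (model$use_last_occurrence) {
    d <- ck[ck$last_occurrence == "true", , drop = FALSE][1L, ]
    lab <- incidence_row(report$id, model$condition,
                         if (d$present == "true") "positive" else "negative",
                         d$start, d$end, nrow(ck))
  } else {
    pos <- which(ck$present == "true")
    d <- if (length(pos) > 0L) ck[pos[length(pos)], ] else ck[nrow(ck), ]
    lab <- incidence_row(report$id, model$condition,
                         if (length(pos) > 0L) "positive" else "negative",
                         d$start, d$end, nrow(ck))
  }
  if (return_doc) list(label = lab, doc = doc) else lab
}

#' Classify every report in a corpus
#'
#' @param reports Data frame of reports (as from [read_reports()] or
#'   [generate_corpus()]).
#' @param model A [condition_model()].
#' @param dictionaries Named list of dictionaries; defaults to the built-ins
#'   the model requires.
#' @param keep_docs Keep the annotated documents (needed for
#'   [build_index()])? Default `FALSE`.
#' @return A list with `labels` (data frame, one row per report) and `docs`
#'   (named list of `rad_doc` or `NULL` entries when `keep_docs`).
#' @export
classify_corpus <- function(reports, model,
                            dictionaries = builtin_dictionaries(model),
                            keep_docs = FALSE) {
  n <- nrow(reports)
  labels <- vector("list", n)
  docs <- if (keep_docs) vector("list", n) else NULL
  for (i in seq_len(n)) {
    res <- classify_report(reports[i, ], model, dictionaries,
                           return_doc = keep_docs)
    if (keep_docs) {
      labels[[i]] <- res$label
      docs[[i]] <- res$doc
    } else {
      labels[[i]] <- res
    }
  }
  labels <- if (n > 0L) do.call(rbind, labels) else incidence_row(
    character(), character(), character(), integer(), integer(), integer())
  if (keep_docs && n > 0L) names(docs) <- labels$report_id
  list(labels = labels, docs = docs)
}

#' Read a condition model from a YAML file
#'
#' The file names the condition, keyword mode, dictionary roles, flags, and
#' (optionally) per-role dictionary files resolved relative to the model
#' file. See the two configurations shipped under
#' `system.file("extdata", "models", package = "radincidence")`.
#'
#' @param path Model YAML file.
#' @return A `condition_model` with attribute `dictionary_files` (named
#'   character vector of resolved paths, possibly empty).
#' @export
read_condition_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  cfg <- yaml::read_yaml(path)
  model <- condition_model(
    condition = cfg$condition,
    keyword_mode = cfg$keyword_mode %||% "cohesive",
    condition_dict = cfg$condition_dictionary,
    dict1 = cfg$dict1, dict2 = cfg$dict2,
    paired_max_gap = cfg$paired_max_gap %||% Inf,
    negative_dicts = unlist(cfg$negative_dictionaries),
    use_ordered_post_indicator = isTRUE(cfg$use_ordered_post_indicator),
    use_last_occurrence = !isFALSE(cfg$use_last_occurrence),
    recall_over_precision = isTRUE(cfg$recall_over_precision),
    title_filter = if (length(cfg$title_filter)) unlist(cfg$title_filter)
  )
  files <- character()
  if (length(cfg$dictionary_files)) {
    files <- vapply(cfg$dictionary_files, identity, character(1))
    rel <- !file.exists(files)
    files[rel] <- file.path(dirname(path), files[rel])
  }
  attr(model, "dictionary_files") <- files
  model
}

#' Load a model together with its dictionaries
#'
#' Roles listed in the model file's `dictionary_files` are loaded from those
#' files; any remaining required role falls back to the package built-ins.
#'
#' @param path Model YAML file.
#' @return List with components `model` and `dictionaries`.
#' @export
load_condition_model <- function(path) {
  model <- read_condition_model(path)
  files <- attr(model, "dictionary_files")
  dicts <- list()
  for (role in required_roles(model)) {
    dicts[[role]] <- if (role %in% names(files)) {
      load_dictionary(files[[role]], role, case_fold = TRUE, locale_map = TRUE)
    } else {
      builtin_dictionary(role)
    }
  }
  list(model = model, dictionaries = dicts)
}

#' Built-in condition models
#'
#' Loads one of the two shipped model configurations: the cohesive-keyword
#' hydronephrosis model or the paired-dictionary brain-metastasis model.
#'
#' @param name `"hydronephrosis"` or `"brain_metastasis"`.
#' @return A `condition_model`.
#' @export
builtin_condition_model <- function(name = c("hydronephrosis",
                                             "brain_metastasis")) {
  name <- match.arg(name)
  read_condition_model(system.file("extdata", "models",
                                   paste0(name, ".yaml"),
                                   package = "radincidence"))
}

#' Load the built-in dictionaries a model requires
#'
#' @param model A [condition_model()] whose roles all name built-ins.
#' @return Named list of [rad_dictionary()] objects.
#' @export
builtin_dictionaries <- function(model) {
  roles <- required_roles(model)
  stats::setNames(lapply(roles, builtin_dictionary), roles)
}

#' Quick single-text classification
#'
#' Convenience wrapper: classify one text with a built-in model, optionally
#' overriding model flags.
#'
#' @param text Report text.
#' @param condition `"hydronephrosis"` or `"brain_metastasis"`.
#' @param title Optional report title.
#' @param recall_over_precision,use_last_occurrence Optional flag overrides.
#' @return The one-row label data frame from [classify_report()].
#' @examples
#' classify_text("Moderate hydronephrosis is noted.")$label
#' @export
classify_text <- function(text, condition = "hydronephrosis", title = NA,
                          recall_over_precision = NULL,
                          use_last_occurrence = NULL) {
  model <- builtin_condition_model(condition)
  if (!is.null(recall_over_precision)) {
    model$recall_over_precision <- recall_over_precision
  }
  if (!is.null(use_last_occurrence)) {
    model$use_last_occurrence <- use_last_occurrence
  }
  classify_report(list(id = "doc1", title = title, text = text),
                  model, builtin_dictionaries(model))
}

#' Write incidence labels as JSON lines
#'
#' One JSON object per report with the report id, condition, label, and the
#' deciding-mention character offsets (null when absent).
#'
#' @param labels Label data frame from [classify_corpus()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(labels))) {
    rec <- list(report_id = labels$report_id[i],
                condition = labels$condition[i],
                label = labels$label[i],
                deciding_start = labels$deciding_start[i],
                deciding_end = labels$deciding_end[i],
                n_mentions = labels$n_mentions[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                digits = NA),
               con, useBytes = TRUE)
  }
  invisible(path)
}
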
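#' Precision and recall against a gold standard
#'
#' Treats `"positive"` as the positive class. Precision = TP/(TP+FP),
#' recall = TP/(TP+FN); a zero denominator yields `NA` ("absent"), never 0.
#' Every gold id must have a prediction and vice versa.
#'
#' @param predictions Data frame with columns `report_id`, `label`.
#' @param gold Data frame with columns `report_id`, `gold_label`.
#' @return List with `precision`, `recall`, and integer `counts`
#'   (`TP`, `FP`, `TN`, `FN`).
#' @examples
#' compute_metrics(
#'   data.frame(report_id = c("a", "b"), label = c("positive", "negative")),
#'   data.frame(report_id = c("a", "b"), gold_label = c("positive", "negative")))
#' @export
compute_metrics <- function(predictions, gold) {
  miss_p <- setdiff(gold$report_id, predictions$report_id)
  miss_g <- setdiff(predictions$report_id, gold$report_id)
  if (length(miss_p) > 0L || length(miss_g) > 0L) {
    stop("prediction/gold id mismatch: ",
         if (length(miss_p)) paste0("no prediction for [",
                                    paste(utils::head(miss_p, 5L), collapse = ", "), "] "),
         if (length(miss_g)) paste0("no gold for [",
                                    paste(utils::head(miss_g, 5L), collapse = ", "), "]"))
  }
  m <- merge(predictions[, c("report_id", "label")],
             gold[, c("report_id", "gold_label")], by = "report_id")
  pred_pos <- m$label == "positive"
  gold_pos <- m$gold_label == "positive"
  counts <- c(TP = sum(pred_pos & gold_pos),
              FP = sum(pred_pos & !gold_pos),
              TN = sum(!pred_pos & !gold_pos),
              FN = sum(!pred_pos & gold_pos))
  ratio <- function(num, den) if (den > 0L) num / den else NA_real_
  list(precision = ratio(counts[["TP"]], counts[["TP"]] + counts[["FP"]]),
       recall = ratio(counts[["TP"]], counts[["TP"]] + counts[["FN"]]),
       counts = counts)
}

#' Draw a stratified review sample
#'
#' The study protocol: sample, without replacement and uniformly within each
#' stratum, `k_pos` reports predicted positive and `k_neg` predicted
#' negative; the export lists the sampled reports in shuffled order without
#' their predicted labels, so the reviewer annotates blind.
#'
#' @param predictions Data frame with columns `report_id`, `label`.
#' @param k_pos,k_neg Stratum sample sizes (an undersized pool is an error
#'   naming the stratum).
#' @param seed Integer seed; the draw is deterministic per seed.
#' @param reports Optional reports data frame; when given, the export carries
#'   the report text alongside the id.
#' @return A `review_sample`: list with `positive_ids`, `negative_ids`,
#'   `export` (label-blind data frame), and `seed`.
#' @export
sample_for_review <- function(predictions, k_pos, k_neg, seed,
                              reports = NULL) {
  pos_pool <- predictions$report_id[predictions$label == "positive"]
  neg_pool <- predictions$report_id[predictions$label == "negative"]
  if (length(pos_pool) < k_pos) {
    stop("predicted-positive pool too small: ", length(pos_pool), " < ", k_pos)
  }
  if (length(neg_pool) < k_neg) {
    stop("predicted-negative pool too small: ", length(neg_pool), " < ", k_neg)
  }
  res <- with_seed(seed, {
    pos <- if (k_pos > 0L) sample(pos_pool, k_pos) else character()
    neg <- if (k_neg > 0L) sample(neg_pool, k_neg) else character()
    all_ids <- c(pos, neg)
    list(pos = pos, neg = neg,
         order = if (length(all_ids)) sample(all_ids) else character())
  })
  export <- data.frame(report_id = res$order, stringsAsFactors = FALSE)
  if (!is.null(reports)) {
    export$text <- reports$text[match(res$order, reports$id)]
  }
  structure(list(positive_ids = res$pos, negative_ids = res$neg,
                 export = export, seed = as.integer(seed)),
            class = "review_sample")
}

#' @export
print.review_sample <- function(x, ...) {
  cat(sprintf("<review_sample: %d predicted-positive + %d predicted-negative, seed %d>\n",
              length(x$positive_ids), length(x$negative_ids), x$seed))
  invisible(x)
}

#' Tabulate misclassified reports for error analysis
#'
#' One row per false positive / false negative with a snippet around the
#' deciding mention (or the report head when there is none) and the
#' generator's pattern tag when the gold file carries one. Iterative
#' dictionary and rule refinement starts from this table.
#'
#' @param predictions Label data frame from [classify_corpus()] (its
#'   `deciding_start`/`deciding_end` columns, when present, anchor the
#'   snippets).
#' @param gold Gold data frame (`report_id`, `gold_label`, optional
#'   `pattern_tag`).
#' @param reports Optional reports data frame supplying text for snippets.
#' @param window Tokens of context either side of the deciding mention.
#' @return Data frame (`report_id`, `error_type`, `snippet`, `pattern_tag`)
#'   sorted by error type then id; zero rows for perfect predictions.
#' @export
error_report <- function(predictions, gold, reports = NULL, window = 10L) {
  m <- merge(predictions, gold, by = "report_id")
  m$error_type <- ifelse(m$label == "positive" & m$gold_label == "negative", "FP",
                  ifelse(m$label == "negative" & m$gold_label == "positive", "FN",
                         NA_character_))
  m <- m[!is.na(m$error_type), , drop = FALSE]
  snippet <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    text <- if (!is.null(reports)) {
      reports$text[match(m$report_id[i], reports$id)]
    } else NA_character_
    if (is.na(text)) { snippet[i] <- ""; next }
    toks <- tokenize(text)
    ds <- if ("deciding_start" %in% names(m)) m$deciding_start[i] else NA
    if (!is.na(ds)) {
      at <- which(toks$start < m$deciding_end[i] & toks$end > ds)
      w0 <- max(1L, min(at) - window)
      w1 <- min(nrow(toks), max(at) + window)
    } else {
      w0 <- 1L
      w1 <- min(nrow(toks), 2L * window + 1L)
    }
    snippet[i] <- substr(text, toks$start[w0] + 1L, toks$end[w1])
  }
  out <- data.frame(
    report_id = m$report_id, error_type = m$error_type, snippet = snippet,
    pattern_tag = if ("pattern_tag" %in% names(m)) m$pattern_tag else
      rep(NA_character_, nrow(m)),
    stringsAsFactors = FALSE)
  out <- out[order(out$error_type, out$report_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
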
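#' Run the full incidence pipeline
#'
#' Orchestrates ingest, lexicon loading, annotation + classification,
#' indexing, and (when gold labels are supplied) evaluation. Each stage logs
#' its counts; any stage error removes partial outputs and raises an error
#' naming the stage. Given the same configuration and seed the outputs are
#' reproducible byte for byte.
#'
#' @param config Either a YAML file path or a list with fields:
#'   `reports` (path, or list with `path` and `format`), `model` (built-in
#'   model name or a model YAML path), `out_dir`, optional `gold` (gold TSV
#'   path), optional `seed` (recorded in the log; default 1), optional
#'   `facets` (extra annotation labels to index), and optional flag overrides
#'   `recall_over_precision`, `use_last_occurrence`, `title_filter`.
#' @return Invisibly, a list with the artifact paths and per-stage counts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out_dir %||% stop("config needs 'out_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  made <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(made)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  log <- list(seed = as.integer(config$seed %||% 1L))

  reports <- stage("ingest", {
    rp <- config$reports
    if (is.character(rp)) rp <- list(path = rp, format = "jsonlines")
    read_reports(rp$path, rp$format %||% "jsonlines")
  })
  log$documents_read <- nrow(reports)

  loaded <- stage("lexicon", {
    mref <- config$model %||% stop("config needs 'model'")
    if (mref %in% c("hydronephrosis", "brain_metastasis")) {
      model <- builtin_condition_model(mref)
      dicts <- builtin_dictionaries(model)
    } else {
      lm <- load_condition_model(mref)
      model <- lm$model
      dicts <- lm$dictionaries
    }
    for (flag in c("recall_over_precision", "use_last_occurrence",
                   "title_filter")) {
      if (!is.null(config[[flag]])) model[[flag]] <- config[[flag]]
    }
    list(model = model, dicts = dicts)
  })

  cls <- stage("classify", {
    classify_corpus(reports, loaded$model, loaded$dicts, keep_docs = TRUE)
  })
  log$annotations_created <- sum(vapply(cls$docs, function(d) {
    if (is.null(d)) 0L else nrow(d$annotations)
  }, integer(1)))
  log$positives <- sum(cls$labels$label == "positive")

  paths <- list(labels = file.path(out_dir, "labels.jsonl"),
                summary = file.path(out_dir, "summary.tsv"),
                index = file.path(out_dir, "index.json"),
                log = file.path(out_dir, "log.json"))
  stage("export", {
    write_labels(cls$labels, paths$labels)
    made <- c(made, paths$labels)
    utils::write.table(cls$labels, paths$summary, sep = "\t",
                       row.names = FALSE, quote = TRUE, qmethod = "double",
                       fileEncoding = "UTF-8")
    made <- c(made, paths$summary)
  })

  stage("index", {
    idx <- build_index(cls$docs, cls$labels,
                       facets = config$facets %||% character())
    write_facet_index(idx, paths$index)
    made <- c(made, paths$index)
  })

  if (!is.null(config$gold)) {
    stage("evaluate", {
      gold <- read_gold(config$gold)
      metrics <- compute_metrics(cls$labels, gold)
      paths$metrics <- file.path(out_dir, "metrics.json")
      jsonlite::write_json(
        list(precision = metrics$precision, recall = metrics$recall,
             counts = as.list(metrics$counts)),
        paths$metrics, auto_unbox = TRUE, digits = NA, na = "null")
      made <- c(made, paths$metrics)
      errs <- error_report(cls$labels, gold, reports)
      paths$errors <- file.path(out_dir, "errors.tsv")
      utils::write.table(errs, paths$errors, sep = "\t", row.names = FALSE,
                         quote = TRUE, qmethod = "double",
                         fileEncoding = "UTF-8")
      made <- c(made, paths$errors)
      log$metrics <- list(precision = metrics$precision,
                           recall = metrics$recall)
    })
  }

  stage("log", {
    cfg_file <- tempfile()
    # digest the analytic configuration; the output location is not part of it
    core <- config[setdiff(names(config), "out_dir")]
    writeLines(paste(deparse(core), collapse = "\n"), cfg_file)
    log$config_digest <- unname(tools::md5sum(cfg_file))
    unlink(cfg_file)
    jsonlite::write_json(log, paths$log, auto_unbox = TRUE, digits = NA,
                         na = "null")
  })
  invisible(list(paths = paths, log = log, labels = cls$labels))
}
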
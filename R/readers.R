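#' Read a corpus of reports
#'
#' Supported formats: `delimited` (comma- or tab-separated with a header row;
#' required column `text`, optional `id` (defaults to the row number),
#' `title`, `locale`; RFC 4180 quoting), `jsonlines` (one JSON object per
#' line with keys `id`/`title`/`text`/`locale`; `id` is required), and
#' `textdir` (one report per `.txt` file, id = file name stem).
#'
#' @param path File (or, for `textdir`, directory) to read.
#' @param format One of `"delimited"`, `"jsonlines"`, `"textdir"`.
#' @return A data frame with character columns `id`, `title`, `text`,
#'   `locale`, one row per report, in file order. Duplicate ids are an error.
#' @export
read_reports <- function(path, format = c("delimited", "jsonlines", "textdir")) {
  format <- match.arg(format)
  out <- switch(format,
    delimited = read_reports_delimited(path),
    jsonlines = read_reports_jsonlines(path),
    textdir = read_reports_textdir(path)
  )
  dup <- unique(out$id[duplicated(out$id)])
  if (length(dup) > 0L) {
    stop("duplicate report id(s): ", paste(dup, collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

read_reports_delimited <- function(path) {
  if (!file.exists(path)) stop("reports file not found: ", path)
  first <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
  sep <- if (grepl("\\.(tsv|tab)$", path) || grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                      colClasses = "character", comment.char = "",
                      fileEncoding = "UTF-8", stringsAsFactors = FALSE),
    error = function(e) stop("malformed delimited reports file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (!"text" %in% names(df)) {
    stop("delimited reports file must have a 'text' column: ", path)
  }
  id <- if ("id" %in% names(df)) df$id else as.character(seq_len(nrow(df)))
  bad <- which(is.na(id) | !nzchar(id))
  if (length(bad) > 0L) stop("record ", bad[1L], ": empty or missing id")
  data.frame(
    id = id,
    title = if ("title" %in% names(df)) df$title else NA_character_,
    text = df$text,
    locale = if ("locale" %in% names(df)) df$locale else "unknown",
    stringsAsFactors = FALSE
  )
}

read_reports_jsonlines <- function(path) {
  if (!file.exists(path)) stop("reports file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  recs <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) stop("malformed JSON on line ", i, ": ",
                                             conditionMessage(e), call. = FALSE))
    if (is.null(rec$id) || is.na(rec$id[1]) || !nzchar(as.character(rec$id[1]))) {
      stop("line ", i, ": record missing 'id'")
    }
    recs[[k]] <- data.frame(
      id = as.character(rec$id),
      title = if (is.null(rec$title)) NA_character_ else as.character(rec$title),
      text = if (is.null(rec$text)) "" else as.character(rec$text),
      locale = if (is.null(rec$locale)) "unknown" else as.character(rec$locale),
      stringsAsFactors = FALSE
    )
  }
  if (length(recs) == 0L) {
    return(data.frame(id = character(), title = character(), text = character(),
                      locale = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, recs)
}

read_reports_textdir <- function(path) {
  if (!dir.exists(path)) stop("reports directory not found: ", path)
  files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
  data.frame(
    id = sub("\\.txt$", "", basename(files)),
    title = NA_character_,
    text = vapply(files, function(f) {
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    }, character(1), USE.NAMES = FALSE),
    locale = "unknown",
    stringsAsFactors = FALSE
  )
}

#' Write a corpus of reports
#'
#' The delimited writer quotes every text field so embedded commas, quotes,
#' and newlines round-trip losslessly.
#'
#' @param reports Data frame with columns `id`, `title`, `text`, `locale`.
#' @param path Output file.
#' @param format `"jsonlines"` or `"delimited"` (CSV).
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path, format = c("jsonlines", "delimited")) {
  format <- match.arg(format)
  if (format == "jsonlines") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (i in seq_len(nrow(reports))) {
      rec <- list(id = reports$id[i], text = reports$text[i])
      if (!is.na(reports$title[i])) rec$title <- reports$title[i]
      rec$locale <- reports$locale[i]
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, useBytes = TRUE)
    }
  } else {
    utils::write.csv(reports, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}
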
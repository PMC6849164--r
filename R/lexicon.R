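uk_us_variants <- function() {
  if (is.null(.radenv$variants)) {
    path <- system.file("extdata", "variants", "uk_us.tsv",
                        package = "radincidence")
    tab <- utils::read.delim(path, colClasses = "character",
                             comment.char = "#", fileEncoding = "UTF-8")
    .radenv$variants <- stats::setNames(tab$us, tab$uk)
  }
  .radenv$variants
}

#' Normalize token surface forms
#'
#' Case-folds and, when `locale_map` is on, maps UK spelling variants to
#' their US canonical forms via the bundled variant table (tumour -> tumor,
#' oedema -> edema, ...), so one dictionary serves reports from either
#' locale.
#'
#' @param x Character vector of token surface forms.
#' @param case_fold Lower-case before matching? Default `TRUE`.
#' @param locale_map Map UK variants to US canonical forms? Default `FALSE`.
#' @return Character vector of normalized forms.
#' @examples
#' normalize_tokens(c("HYDRONEPHROSIS", "tumour"), locale_map = TRUE)
#' @export
normalize_tokens <- function(x, case_fold = TRUE, locale_map = FALSE) {
  if (case_fold) x <- tolower(x)
  if (locale_map) {
    v <- uk_us_variants()
    m <- v[x]
    x[!is.na(m)] <- m[!is.na(m)]
  }
  x
}

#' Construct a dictionary of terms
#'
#' A dictionary is a named set of (possibly multiword) terms used to create
#' annotations by token-sequence matching. Terms are tokenized with the same
#' scanner as report text, normalized under the dictionary's match policy,
#' and de-duplicated.
#'
#' @param name Dictionary name; becomes the annotation label of its matches
#'   (e.g. `"NegationIndicator"`).
#' @param terms Character vector of term phrases.
#' @param canonical Optional character vector of canonical forms, recycled
#'   against `terms`; defaults to the lower-cased space-joined phrase.
#' @param case_fold,locale_map Match policy, see [normalize_tokens()].
#' @return An object of class `rad_dictionary`.
#' @export
rad_dictionary <- function(name, terms, canonical = NULL,
                           case_fold = TRUE, locale_map = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  terms <- terms[!is.na(terms) & nzchar(trimws(terms))]
  phrases <- lapply(terms, function(t) tokenize(t)$surface)
  keep <- lengths(phrases) > 0L
  phrases <- phrases[keep]
  terms <- terms[keep]
  if (length(phrases) == 0L) {
    stop("dictionary '", name, "' must contain at least one term")
  }
  norm <- lapply(phrases, normalize_tokens,
                 case_fold = case_fold, locale_map = locale_map)
  canon <- if (is.null(canonical)) {
    vapply(norm, paste, character(1), collapse = " ")
  } else {
    ifelse(is.na(canonical) | !nzchar(canonical),
           vapply(norm, paste, character(1), collapse = " "),
           tolower(canonical))
  }
  key <- vapply(norm, paste, character(1), collapse = "")
  first <- !duplicated(key)
  structure(
    list(name = name, phrases = norm[first], canonical = canon[first],
         case_fold = case_fold, locale_map = locale_map),
    class = "rad_dictionary"
  )
}

#' @export
print.rad_dictionary <- function(x, ...) {
  cat(sprintf("<rad_dictionary %s: %d terms%s%s>\n", x$name,
              length(x$phrases),
              if (x$case_fold) ", case-folded" else "",
              if (x$locale_map) ", UK/US mapped" else ""))
  invisible(x)
}

#' Load a dictionary from a plain-text file
#'
#' One term per line, UTF-8, `#`-prefixed comments allowed; a line of the
#' form `term|canonical` overrides the default canonical form. An empty
#' dictionary is an error: every model dictionary must have at least one
#' term.
#'
#' @param path Dictionary file.
#' @inheritParams rad_dictionary
#' @return A `rad_dictionary`.
#' @export
load_dictionary <- function(path, name, case_fold = TRUE, locale_map = FALSE) {
  if (!file.exists(path)) stop("dictionary file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("dictionary '", name, "' is empty: ", path)
  }
  parts <- strsplit(lines, "|", fixed = TRUE)
  terms <- vapply(parts, `[`, character(1), 1L)
  canon <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                  character(1))
  rad_dictionary(name, terms, canonical = canon,
                 case_fold = case_fold, locale_map = locale_map)
}

# Built-in dictionary roles shipped under inst/extdata/dictionaries.
.builtin_dicts <- c(
  HydronephrosisKeyword = "hydronephrosis_keywords.txt",
  BrainKeyword = "brain_keywords.txt",
  MetastasisKeyword = "metastasis_keywords.txt",
  NegationIndicator = "negation.txt",
  EvaluationIndicator = "evaluation.txt",
  HistoryIndicator = "history.txt",
  ResolutionIndicator = "resolution.txt",
  BodyOrgan = "body_organ.txt",
  Cancer = "cancer.txt",
  Gender = "gender.txt"
)

#' Load one of the dictionaries shipped with the package
#'
#' Starter dictionaries (user-editable data files under
#' `inst/extdata/dictionaries/`) for the two condition models and the
#' negative-instance indicator types. All built-ins case-fold and apply the
#' UK/US variant map.
#'
#' @param role One of `r paste0('"', names(.builtin_dicts), '"', collapse = ", ")`.
#' @return A `rad_dictionary`.
#' @export
builtin_dictionary <- function(role) {
  if (!role %in% names(.builtin_dicts)) {
    stop("unknown built-in dictionary role: ", role)
  }
  path <- system.file("extdata", "dictionaries", .builtin_dicts[[role]],
                      package = "radincidence")
  load_dictionary(path, role, case_fold = TRUE, locale_map = TRUE)
}

#' Match dictionary terms in a report
#'
#' Scans normalized token sequences sentence by sentence; every maximal
#' in-sentence token subsequence equal to a term phrase yields one
#' annotation. Longest match wins: a match strictly contained in another
#' match from the same dictionary is suppressed. Equal-length overlaps and
#' matches from different dictionaries are all kept.
#'
#' @param doc A `rad_doc` from [annotate_report()] (annotations may be empty).
#' @param dict A `rad_dictionary`.
#' @return An annotation data frame (possibly empty) with `label = dict$name`.
#' @export
match_terms <- function(doc, dict) {
  toks <- doc$tokens
  if (nrow(toks) == 0L) return(empty_annotations())
  norm <- normalize_tokens(toks$surface, dict$case_fold, dict$locale_map)
  ts <- integer(); te <- integer(); canon <- character()
  for (s in seq_len(nrow(doc$sentences))) {
    a <- doc$sentences$token_start[s]
    b <- doc$sentences$token_end[s]
    for (ti in seq_along(dict$phrases)) {
      ph <- dict$phrases[[ti]]
      L <- length(ph)
      if (L > b - a + 1L) next
      if (L == 1L) {
        hits <- which(norm[a:b] == ph) + a - 1L
      } else {
        hits <- integer()
        for (i in a:(b - L + 1L)) {
          if (all(norm[i:(i + L - 1L)] == ph)) hits <- c(hits, i)
        }
      }
      if (length(hits) > 0L) {
        ts <- c(ts, hits)
        te <- c(te, hits + L - 1L)
        canon <- c(canon, rep(dict$canonical[ti], length(hits)))
      }
    }
  }
  if (length(ts) == 0L) return(empty_annotations())
  # suppress matches strictly contained in a longer match from this dictionary
  n <- length(ts)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && ts[j] <= ts[i] && te[j] >= te[i] &&
          (te[j] - ts[j]) > (te[i] - ts[i])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  ts <- ts[keep]; te <- te[keep]; canon <- canon[keep]
  sort_annotations(new_annotations(
    label = dict$name,
    start = toks$start[ts], end = toks$end[te],
    sentence = doc$tok_sentence[ts],
    token_start = ts, token_end = te,
    provenance = paste0("dict:", dict$name, ":", canon)
  ))
}
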
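# Filler sentences: a closed vocabulary of neutral radiology phrases that is
# disjoint from every shipped dictionary, so distractor content is a true
# negative by construction.
.filler_body <- c(
  "The visualized solid organs appear unremarkable.",
  "Both kidneys are normal in size and position.",
  "The bladder is well distended with a smooth outline.",
  "The liver spleen and pancreas appear within normal limits.",
  "Degenerative change is seen in the lumbar spine.",
  "The bowel gas pattern is unremarkable.",
  "Both ureters appear normal in caliber.",
  "The visualized lung bases are clear.",
  "Soft tissues are unremarkable in appearance.",
  "The aorta is normal in caliber throughout.",
  "Incidental simple cortical cyst on the left.",
  "The gallbladder is thin walled.",
  "Vascular calcification is present in the pelvis.",
  "Alignment of the spine is preserved.",
  "The adrenal glands are unremarkable bilaterally."
)

.filler_head <- c(
  "The ventricles are normal in size and configuration.",
  "Gray white matter differentiation is preserved.",
  "The basal cisterns are patent.",
  "Midline structures are in normal position.",
  "The paranasal sinuses are clear.",
  "The calvarium is intact.",
  "The orbits are unremarkable.",
  "Major vascular flow voids are preserved.",
  "The extracranial soft tissues are unremarkable.",
  "The sella and pituitary region appear normal."
)

.complaints <- list(
  hydronephrosis = c("flank pain", "renal colic", "abdominal discomfort",
                     "raised creatinine", "urinary symptoms"),
  brain_metastasis = c("headache", "new onset seizure", "confusion",
                       "staging", "unsteady gait")
)

.titles <- list(
  hydronephrosis = c("US Renal Tract", "CT Abdomen Pelvis", "CT Urogram"),
  brain_metastasis = c("CT Head", "MRI Brain")
)

# Condition-keyword slots (hydronephrosis, cohesive mode).
.hydro_kw <- c("hydronephrosis", "hydroureteronephrosis",
               "pelvicalyceal dilatation", "dilated renal pelvis")
.degrees <- c("mild", "moderate", "severe", "slight")

# Paired slots (brain metastasis): a brain-related word and a
# metastasis-indicating phrase that must co-occur within one sentence.
.brain_words <- c("brain", "cerebral", "cerebellar", "intracranial")
.met_plural <- list(UK = c("metastases", "metastatic deposits", "deposits",
                           "lesions", "tumours"),
                    US = c("metastases", "metastatic deposits", "deposits",
                           "lesions", "tumors"))
.met_singular <- list(UK = c("metastasis", "metastatic deposit", "tumour"),
                      US = c("metastasis", "metastatic deposit", "tumor"))

.pattern_gold <- c(
  plain_positive = "positive", paired_positive = "positive",
  negated = "negative", evaluation_header = "negative",
  history = "negative", resolution = "negative",
  modality_then_negated_impression = "negative",
  paired_split_sentences = "negative",
  distractor_no_keyword = "negative",
  implicit_negation = "negative"
)

default_template_mix <- function(condition) {
  if (condition == "hydronephrosis") {
    c(plain_positive = 0.30, negated = 0.16, evaluation_header = 0.10,
      history = 0.10, resolution = 0.06,
      modality_then_negated_impression = 0.08, distractor_no_keyword = 0.20)
  } else {
    c(paired_positive = 0.30, paired_split_sentences = 0.12, negated = 0.12,
      evaluation_header = 0.08, history = 0.08, resolution = 0.05,
      modality_then_negated_impression = 0.05, distractor_no_keyword = 0.20)
  }
}

#' Define a synthetic-corpus profile
#'
#' A profile fixes the statistical shape of a generated corpus: locale (UK
#' reports average about 70 tokens, US about 206, with UK/US spellings and
#' indication verbs to match), condition, mean report length, the mix of
#' incidence patterns (each pattern determines its gold label), and the
#' fraction of adversarial implicit-negation reports the rules cannot
#' handle.
#'
#' @param condition `"hydronephrosis"` or `"brain_metastasis"`.
#' @param locale `"UK"` or `"US"`.
#' @param mean_length_tokens Mean report length in tokens; defaults to 70
#'   (UK) or 206 (US).
#' @param template_mix Named probability vector over pattern tags (must sum
#'   to 1); defaults to a condition-appropriate mix.
#' @param adversarial_fraction Fraction `q` of reports drawn from the
#'   implicit-negation pattern ("the patient denies ..."), replacing a
#'   proportional share of the regular mix. Default 0.
#' @return A `corpus_profile`.
#' @export
corpus_profile <- function(condition = c("hydronephrosis", "brain_metastasis"),
                           locale = c("UK", "US"),
                           mean_length_tokens = NULL,
                           template_mix = NULL,
                           adversarial_fraction = 0) {
  condition <- match.arg(condition)
  locale <- match.arg(locale)
  if (is.null(mean_length_tokens)) {
    mean_length_tokens <- if (locale == "UK") 70 else 206
  }
  stopifnot(mean_length_tokens > 0,
            adversarial_fraction >= 0, adversarial_fraction < 1)
  mix <- template_mix %||% default_template_mix(condition)
  if (abs(sum(mix) - 1) > 1e-8) stop("template_mix must sum to 1")
  if (!all(names(mix) %in% names(.pattern_gold))) {
    stop("unknown pattern tag(s): ",
         paste(setdiff(names(mix), names(.pattern_gold)), collapse = ", "))
  }
  if (adversarial_fraction > 0) {
    mix <- c(mix * (1 - adversarial_fraction),
             implicit_negation = adversarial_fraction)
  }
  structure(
    list(condition = condition, locale = locale,
         mean_length_tokens = mean_length_tokens, template_mix = mix,
         adversarial_fraction = adversarial_fraction),
    class = "corpus_profile"
  )
}

# Pattern realisations. Each returns list(reason, findings, impression) of
# sentences; NULL reason/impression fall back to neutral defaults.
instantiate_pattern <- function(tag, profile) {
  us <- profile$locale == "US"
  if (profile$condition == "hydronephrosis") {
    kw <- sample(.hydro_kw, 1L)
    deg <- sample(.degrees, 1L)
    phr <- list(
      plain_positive = list(findings = sample(c(
        sprintf("%s %s is noted on the right.", toupper_first(deg), kw),
        sprintf("There is %s %s on the left.", deg, kw),
        sprintf("%s is demonstrated bilaterally.", toupper_first(kw))), 1L)),
      negated = list(findings = sample(c(
        sprintf("There is no %s.", kw),
        sprintf("There is no evidence of %s.", kw),
        sprintf("The right kidney is low lying but without frank %s.", kw)), 1L)),
      evaluation_header = list(reason = if (us) {
        sprintf("Indication: Assess for %s.", kw)
      } else {
        sprintf("Reason: Evaluate for %s.", kw)
      }),
      history = list(findings = sample(c(
        sprintf("Known %s under surveillance.", kw),
        sprintf("Previously demonstrated %s under review.", kw)), 1L)),
      resolution = list(findings = sample(c(
        sprintf("Interval resolution of the documented %s.", kw),
        sprintf("Resolved %s with normal appearances.", kw)), 1L)),
      modality_then_negated_impression = list(
        findings = sprintf("Initial images raised the possibility of %s %s.",
                           deg, kw),
        impression = sprintf("No definite %s.", kw)),
      distractor_no_keyword = list(),
      implicit_negation = list(findings = sprintf(
        "The patient denies %s and %s was excluded at clinical review.",
        sample(c("flank pain", "any discomfort"), 1L), kw))
    )
  } else {
    b <- sample(.brain_words, 1L)
    mp <- sample(.met_plural[[profile$locale]], 1L)
    ms <- sample(.met_singular[[profile$locale]], 1L)
    phr <- list(
      paired_positive = list(findings = sample(c(
        sprintf("Within the %s multiple ring enhancing %s are noted.", b, mp),
        sprintf("Multiple enhancing %s are seen within the %s.", mp, b)), 1L)),
      paired_split_sentences = list(findings = c(
        sprintf("The %s is otherwise unremarkable.", b),
        sprintf("Sclerotic %s are seen in the bony spine.", mp))),
      negated = list(findings = sample(c(
        sprintf("There is no %s %s.", b, ms),
        sprintf("No evidence of %s %s.", b, mp)), 1L)),
      evaluation_header = list(reason = if (us) {
        sprintf("Indication: Assess for %s %s.", b, mp)
      } else {
        sprintf("Reason: Evaluate for %s %s.", b, mp)
      }),
      history = list(findings = sprintf("Known %s %s under surveillance.",
                                        b, mp)),
      resolution = list(findings = sprintf(
        "Interval resolution of the treated %s %s.", b, mp)),
      modality_then_negated_impression = list(
        findings = sprintf("Initial images raised the possibility of %s %s.",
                           b, mp),
        impression = sprintf("No definite %s %s.", b, ms)),
      distractor_no_keyword = list(),
      implicit_negation = list(findings = sprintf(
        "The patient denies headache and %s %s were excluded at clinical review.",
        b, mp))
    )
  }
  phr[[tag]] %||% list()
}

toupper_first <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substr(x, 2L, nchar(x)))
}

filler_token_counts <- function(pool) {
  key <- paste0("flen_", substr(pool[1L], 1L, 8L), length(pool))
  if (is.null(.radenv[[key]])) {
    .radenv[[key]] <- vapply(pool, function(s) nrow(tokenize(s)), integer(1),
                             USE.NAMES = FALSE)
  }
  .radenv[[key]]
}

#' Generate one synthetic report
#'
#' Assembles a report from section templates (Reason line, FINDINGS,
#' IMPRESSION) with the pattern-mandated sentence(s) slotted into the right
#' section and neutral filler sentences added until the token count reaches a
#' length drawn from a lognormal distribution around the profile mean. Uses
#' the caller's RNG state; seed before calling (or use [generate_corpus()]).
#'
#' @param profile A [corpus_profile()].
#' @param id Report id.
#' @param tag Pattern tag; drawn from the profile's template mix when `NULL`.
#' @return List with `report` (id, title, text, locale) and `gold`
#'   (report_id, condition, gold_label, pattern_tag).
#' @export
generate_report <- function(profile, id, tag = NULL) {
  mix <- profile$template_mix
  if (is.null(tag)) tag <- sample(names(mix), 1L, prob = mix)
  parts <- instantiate_pattern(tag, profile)
  head_study <- profile$condition == "brain_metastasis"
  pool <- if (head_study) .filler_head else .filler_body
  pool_len <- filler_token_counts(pool)

  reason <- parts$reason %||% sprintf(
    "%s: %s.", if (profile$locale == "US") "Indication" else "Reason",
    sample(.complaints[[profile$condition]], 1L))
  impression <- parts$impression %||% sample(
    c("Findings as described above.", "Unremarkable study."), 1L)
  findings <- as.character(parts$findings %||% character())

  mlog <- log(profile$mean_length_tokens) - 0.35^2 / 2
  target <- max(15L, round(stats::rlnorm(1L, mlog, 0.35)))
  core <- sum(nrow(tokenize(reason)), nrow(tokenize(impression)),
              vapply(findings, function(s) nrow(tokenize(s)), integer(1)),
              4L)  # the two section headers
  count <- core
  fillers <- character()
  while (count < target - 4L) {
    pick <- sample(length(pool), 1L)
    fillers <- c(fillers, pool[pick])
    count <- count + pool_len[pick]
  }
  # pattern sentences at a random position among the fillers
  body <- fillers
  if (length(findings) > 0L) {
    at <- sample(length(body) + 1L, 1L)
    body <- append(body, findings, after = at - 1L)
  }
  text <- paste0(reason, "\n",
                 "FINDINGS: ", paste(body, collapse = " "), "\n",
                 "IMPRESSION: ", impression)
  list(
    report = list(id = id, title = sample(.titles[[profile$condition]], 1L),
                  text = text, locale = profile$locale),
    gold = list(report_id = id, condition = profile$condition,
                gold_label = unname(.pattern_gold[tag]), pattern_tag = tag)
  )
}

#' Generate a labeled synthetic corpus
#'
#' Draws `n` pattern tags from the profile mix and instantiates one report
#' per tag. Output is byte-identical for identical (profile, n, seed). Each
#' pattern tag determines its gold label deterministically, so a corpus built
#' only from rule-covered patterns is recovered perfectly by the matching
#' condition model.
#'
#' @param profile A [corpus_profile()].
#' @param n Number of reports (n >= 0).
#' @param seed Integer seed; all generator randomness derives from it.
#' @param dir Optional output directory; when given, writes `reports.jsonl`,
#'   `gold.tsv`, and `manifest.json`.
#' @return List with `reports` (data frame), `gold` (data frame), `manifest`
#'   (list with per-pattern counts), and `paths` (when `dir` is given).
#' @export
generate_corpus <- function(profile, n, seed, dir = NULL) {
  stopifnot(n >= 0)
  out <- with_seed(seed, {
    tags <- if (n > 0L) {
      sample(names(profile$template_mix), n, replace = TRUE,
             prob = profile$template_mix)
    } else character()
    reports <- vector("list", n)
    gold <- vector("list", n)
    for (i in seq_len(n)) {
      r <- generate_report(profile, sprintf("R%05d", i), tag = tags[i])
      reports[[i]] <- as.data.frame(r$report, stringsAsFactors = FALSE)
      gold[[i]] <- as.data.frame(r$gold, stringsAsFactors = FALSE)
    }
    list(tags = tags, reports = reports, gold = gold)
  })
  empty_rep <- data.frame(id = character(), title = character(),
                          text = character(), locale = character(),
                          stringsAsFactors = FALSE)
  empty_gold <- data.frame(report_id = character(), condition = character(),
                           gold_label = character(), pattern_tag = character(),
                           stringsAsFactors = FALSE)
  reports <- if (n > 0L) do.call(rbind, out$reports) else empty_rep
  gold <- if (n > 0L) do.call(rbind, out$gold) else empty_gold
  counts <- as.list(table(factor(out$tags,
                                 levels = sort(names(profile$template_mix)))))
  counts <- lapply(counts, as.integer)
  manifest <- list(n = as.integer(n), seed = as.integer(seed),
                   condition = profile$condition, locale = profile$locale,
                   mean_length_tokens = profile$mean_length_tokens,
                   adversarial_fraction = profile$adversarial_fraction,
                   pattern_counts = counts)
  res <- list(reports = reports, gold = gold, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(reports = file.path(dir, "reports.jsonl"),
                  gold = file.path(dir, "gold.tsv"),
                  manifest = file.path(dir, "manifest.json"))
    write_reports(reports, paths$reports, "jsonlines")
    utils::write.table(gold, paths$gold, sep = "\t", row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    res$paths <- paths
  }
  res
}

#' Read a gold-label file
#'
#' Accepts the generator's `gold.tsv` or a hand-annotation file in the same
#' delimited format (columns `report_id`, `gold_label`, optionally
#' `condition`, `pattern_tag`).
#'
#' @param path Gold file.
#' @return Data frame of gold labels.
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) stop("gold file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          fileEncoding = "UTF-8")
  if (!all(c("report_id", "gold_label") %in% names(df))) {
    stop("gold file must have 'report_id' and 'gold_label' columns")
  }
  df
}
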
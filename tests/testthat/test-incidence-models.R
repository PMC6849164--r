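test_that("the cohesive model rule set has the expected structure", {
  m <- hydro_model()
  rs <- build_condition_ruleset(m, hydro_dicts())
  # keyword creation + 4 indicator rules + default-positive + last-occurrence
  expect_identical(length(rs$rules), 7L)
  expect_identical(rs$rules[[1]]$action$type, "create")
  expect_identical(rs$rules[[7]]$action$type, "mark_last")
  # recall-over-precision drops exactly the negation rule
  rs2 <- build_condition_ruleset(hydro_model(recall_over_precision = TRUE),
                                 hydro_dicts())
  expect_identical(length(rs2$rules), 6L)
  expect_false(any(grepl("NegationIndicator",
                         vapply(rs2$rules, `[[`, character(1), "id"))))
})

test_that("model invariants are enforced", {
  expect_error(condition_model("x", "cohesive", condition_dict = "D",
                               negative_dicts = character()),
               "at least one")
  expect_error(condition_model("x", "paired", dict1 = "A"), "dict2")
  expect_error(build_condition_ruleset(hydro_model(),
                                       hydro_dicts()["NegationIndicator"]),
               "missing dictionary")
})

test_that("the three printed difficult cases all classify negative", {
  expect_identical(classify_text(table3_case1)$label, "negative")
  expect_identical(classify_text(table3_case2)$label, "negative")
  expect_identical(classify_text(table3_case3)$label, "negative")
})

test_that("recall-over-precision flips the hedged-negation case to positive", {
  expect_identical(classify_text(table3_case2,
                                 recall_over_precision = TRUE)$label,
                   "positive")
  # the evaluation/history case stays negative: only negation is disabled
  expect_identical(classify_text(table3_case1,
                                 recall_over_precision = TRUE)$label,
                   "negative")
})

test_that("plain positive mentions classify positive; absent keywords negative", {
  lab <- classify_text("Moderate hydronephrosis is noted.")
  expect_identical(lab$label, "positive")
  expect_identical(substr("Moderate hydronephrosis is noted.",
                          lab$deciding_start + 1, lab$deciding_end),
                   "hydronephrosis")
  expect_identical(classify_text("Normal kidneys bilaterally.")$label,
                   "negative")
  expect_identical(classify_text("")$label, "negative")
})

test_that("the paired brain model builds sentence-level condition mentions", {
  txt <- "Within the brain multiple ring enhancing metastatic deposits noted"
  res <- classify_report(list(id = "b1", text = txt), brain_model(),
                         brain_dicts(), return_doc = TRUE)
  expect_identical(res$label$label, "positive")
  ck <- res$doc$annotations[res$doc$annotations$label == "ConditionKeyword", ]
  expect_gt(nrow(ck), 0)
  expect_true(all(ck$present == "true"))

  # keywords in different sentences never pair
  split <- "The brain is unremarkable. Multiple deposits in the spine."
  expect_identical(classify_report(list(id = "b2", text = split),
                                   brain_model(), brain_dicts())$label,
                   "negative")
})

test_that("the title filter gates the paired model", {
  m <- brain_model()
  expect_true(apply_title_filter(list(id = "x", title = "CT Head", text = ""), m))
  expect_false(apply_title_filter(list(id = "x", title = "CT Abdomen", text = ""), m))
  expect_true(apply_title_filter(list(id = "x", text = ""), m))
  expect_true(apply_title_filter(list(id = "x", title = "CT Abdomen", text = ""),
                                 hydro_model()))
  # a filtered-out report is negative without rule application
  txt <- "Within the brain multiple metastatic deposits noted"
  lab <- classify_report(list(id = "x", title = "CT Abdomen", text = txt),
                         m, brain_dicts())
  expect_identical(lab$label, "negative")
  expect_identical(lab$n_mentions, 0L)
})

test_that("every condition mention ends with present true or false", {
  set.seed(420)
  prof <- corpus_profile("hydronephrosis", "UK")
  cc <- generate_corpus(prof, 40, seed = 21)
  m <- hydro_model()
  d <- hydro_dicts()
  for (i in seq_len(nrow(cc$reports))) {
    res <- classify_report(cc$reports[i, ], m, d, return_doc = TRUE)
    ck <- res$doc$annotations[res$doc$annotations$label == "ConditionKeyword", ]
    expect_true(all(ck$present %in% c("true", "false")))
    if (nrow(ck) > 0) {
      expect_identical(sum(ck$last_occurrence == "true"), 1L)
    }
  }
})

test_that("prepending a negation can only flip positive to negative", {
  set.seed(430)
  prof <- corpus_profile("hydronephrosis", "UK")
  cc <- generate_corpus(prof, 30, seed = 33)
  m <- hydro_model()
  d <- hydro_dicts()
  for (i in seq_len(nrow(cc$reports))) {
    lab <- classify_report(cc$reports[i, ], m, d)
    if (is.na(lab$deciding_start)) next
    txt <- cc$reports$text[i]
    mod <- paste0(substr(txt, 1, lab$deciding_start), "no ",
                  substr(txt, lab$deciding_start + 1, nchar(txt)))
    lab2 <- classify_report(list(id = "m", text = mod), m, d)
    if (lab$label == "negative") expect_identical(lab2$label, "negative")
  }
})

test_that("with a single mention the last-occurrence flag is irrelevant", {
  texts <- c("Moderate hydronephrosis is noted.",
             "There is no hydronephrosis.",
             "Known hydronephrosis under surveillance.")
  for (t in texts) {
    expect_identical(classify_text(t, use_last_occurrence = TRUE)$label,
                     classify_text(t, use_last_occurrence = FALSE)$label)
  }
})

test_that("model configs round-trip from YAML with dictionaries resolved", {
  lm <- load_condition_model(system.file("extdata", "models",
                                         "brain_metastasis.yaml",
                                         package = "radincidence"))
  expect_identical(lm$model$keyword_mode, "paired")
  expect_identical(lm$model$paired_max_gap, Inf)
  expect_setequal(names(lm$dictionaries),
                  c("BrainKeyword", "MetastasisKeyword", "NegationIndicator",
                    "EvaluationIndicator", "HistoryIndicator",
                    "ResolutionIndicator"))
})
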
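cancer_location_rule <- function(max_gap = 5) {
  rule_spec("cancer-location",
            elements = list(ann_pattern("BodyOrgan"), ann_pattern("Cancer")),
            action = action_create("CancerLocation"),
            scope = "sentence", ordered = FALSE, max_gap = max_gap)
}

organ_cancer_doc <- function(text) {
  annotate_report(list(id = "r", text = text),
                  list(builtin_dictionary("BodyOrgan"),
                       builtin_dictionary("Cancer")))
}

test_that("unordered sentence rule with 5-token gap matches the printed phrases", {
  d1 <- apply_rule(cancer_location_rule(), organ_cancer_doc("breast cancer"))
  expect_identical(sum(d1$annotations$label == "CancerLocation"), 1L)

  d2 <- apply_rule(cancer_location_rule(),
                   organ_cancer_doc("cancer has metastasized to the brain"))
  loc <- d2$annotations[d2$annotations$label == "CancerLocation", ]
  expect_gt(nrow(loc), 0L)
  # the cancer...brain pairing spans the whole printed phrase (gap of 4)
  expect_true(any(loc$start == 0L & loc$end == nchar("cancer has metastasized to the brain")))

  # six intervening tokens exceed the bound
  d3 <- apply_rule(cancer_location_rule(),
                   organ_cancer_doc("cancer that was previously treated at another centre brain"))
  expect_identical(sum(d3$annotations$label == "CancerLocation"), 0L)
})

test_that("ordered negation rule sets present=false on the condition keyword", {
  doc <- annotate_report(
    list(id = "r", text = "without frank hydronephrosis"),
    list(builtin_dictionary("NegationIndicator"),
         rad_dictionary("ConditionKeyword", "hydronephrosis")))
  r <- rule_spec("neg",
                 elements = list(ann_pattern("NegationIndicator"),
                                 ann_pattern("ConditionKeyword")),
                 action = action_set(2, "present", "false"),
                 scope = "sentence", ordered = TRUE)
  doc <- apply_rule(r, doc)
  ck <- doc$annotations[doc$annotations$label == "ConditionKeyword", ]
  expect_identical(ck$present, "false")
})

test_that("a sentence-scoped rule never fires across a sentence boundary", {
  # trigger split over two sentences: indicator in one, keyword in the next
  doc <- annotate_report(
    list(id = "r", text = "There is no obstruction. Hydronephrosis is noted."),
    list(builtin_dictionary("NegationIndicator"),
         rad_dictionary("ConditionKeyword", "hydronephrosis")))
  r <- rule_spec("neg",
                 elements = list(ann_pattern("NegationIndicator"),
                                 ann_pattern("ConditionKeyword")),
                 action = action_set(2, "present", "false"))
  doc <- apply_rule(r, doc)
  ck <- doc$annotations[doc$annotations$label == "ConditionKeyword", ]
  expect_identical(ck$present, "unknown")

  # same for unordered create rules
  d2 <- apply_rule(cancer_location_rule(max_gap = Inf),
                   organ_cancer_doc("The brain is unremarkable. Cancer elsewhere."))
  expect_identical(sum(d2$annotations$label == "CancerLocation"), 0L)
})

test_that("earlier rules win when two rules set the same feature", {
  doc <- annotate_report(list(id = "r", text = "alpha bravo"),
                         list(rad_dictionary("A", "alpha"),
                              rad_dictionary("B", "bravo")))
  rs <- rule_set("prec", list(
    rule_spec("first", list(ann_pattern("A")), action_set(1, "polarity", "negative")),
    rule_spec("second", list(ann_pattern("A")), action_set(1, "polarity", "positive"))))
  doc <- apply_ruleset(rs, doc)
  expect_identical(doc$annotations$polarity[doc$annotations$label == "A"],
                   "negative")
})

test_that("token literals participate in rules", {
  doc <- annotate_report(list(id = "r", text = "Frank hydronephrosis is noted."),
                         list(rad_dictionary("ConditionKeyword", "hydronephrosis")))
  r <- rule_spec("tok",
                 elements = list(token_pattern("frank"),
                                 ann_pattern("ConditionKeyword")),
                 action = action_set(2, "present", "true"))
  doc <- apply_rule(r, doc)
  expect_identical(doc$annotations$present[1], "true")
})

test_that("set-feature on a label outside the inventory is an error", {
  doc <- annotate_report(list(id = "r", text = "alpha"),
                         list(rad_dictionary("A", "alpha")))
  r <- rule_spec("bad", list(ann_pattern("Missing")),
                 action_set(1, "present", "false"))
  expect_error(apply_rule(r, doc), "inventory")
  # a label registered by a create rule is legal even with zero instances
  rs <- rule_set("ok", list(
    rule_spec("make", list(ann_pattern("B")), action_create("Made")),
    rule_spec("set", list(ann_pattern("Made")), action_set(1, "present", "true"))))
  doc$labels <- union(doc$labels, "B")
  expect_no_error(apply_ruleset(rs, doc))
})

test_that("rule application is deterministic and idempotent in its creations", {
  doc <- organ_cancer_doc("breast cancer and liver metastasis in one sentence")
  rs <- rule_set("cl", list(cancer_location_rule(max_gap = Inf)))
  d1 <- apply_ruleset(rs, doc)
  d2 <- apply_ruleset(rs, doc)
  expect_identical(jsonlite::toJSON(d1$annotations, digits = NA),
                   jsonlite::toJSON(d2$annotations, digits = NA))
  # re-applying creates no duplicates
  d3 <- apply_ruleset(rs, d1)
  expect_identical(nrow(d3$annotations), nrow(d1$annotations))
})

test_that("last-occurrence marking selects exactly the final mention", {
  doc <- annotate_report(
    list(id = "r", text = "FINDINGS: hydronephrosis seen. IMPRESSION: No hydronephrosis."),
    list(rad_dictionary("ConditionKeyword", "hydronephrosis")))
  ann <- mark_last_occurrence(doc$annotations, "ConditionKeyword")
  expect_identical(ann$last_occurrence, c("false", "true"))
  expect_identical(which(ann$last_occurrence == "true"),
                   which.max(ann$start))
  # zero mentions: unchanged; one mention: marked true
  expect_identical(mark_last_occurrence(doc$annotations, "Nope"),
                   doc$annotations)
  one <- doc$annotations[1, ]
  expect_identical(mark_last_occurrence(one, "ConditionKeyword")$last_occurrence,
                   "true")
})

test_that("rule engine agrees with the brute-force combination oracle", {
  set.seed(310)
  for (rep in 1:60) {
    text <- random_text(sample(5:40, 1), .test_vocab)
    dA <- random_dictionary("A", .test_vocab, sample(1:4, 1))
    dB <- random_dictionary("B", .test_vocab, sample(1:4, 1))
    doc <- annotate_report(list(id = "r", text = text), list(dA, dB))
    ordered <- sample(c(TRUE, FALSE), 1)
    gap <- sample(c(0, 1, 3, Inf), 1)
    rc <- rule_spec("mk", list(ann_pattern("A"), ann_pattern("B")),
                    action_create("Out"), ordered = ordered, max_gap = gap)
    got <- apply_rule(rc, doc)$annotations
    got <- got[got$label == "Out", c("token_start", "token_end")]
    got <- got[order(got$token_start, got$token_end), ]
    rownames(got) <- NULL
    exp <- oracle_sentence_rule(rc, doc)
    expect_identical(got, exp)

    rs <- rule_spec("set", list(ann_pattern("A"), ann_pattern("B")),
                    action_set(2, "present", "false"),
                    ordered = ordered, max_gap = gap)
    got2 <- apply_rule(rs, doc)$annotations
    got_idx <- which(got2$present == "false")
    expect_identical(as.numeric(got_idx), as.numeric(oracle_sentence_rule(rs, doc)))
  }
})
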
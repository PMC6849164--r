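# Small corpus: two positive, one negated-mention hydronephrosis report, one
# distractor mentioning a gender term.
fixture_index <- function() {
  reports <- data.frame(
    id = c("p1", "p2", "n1", "d1", "d2"),
    title = NA_character_,
    text = c("Moderate hydronephrosis is noted.",
             "Severe hydronephrosis is demonstrated in a female patient.",
             paste0("FINDINGS: slight pelviectasis but without frank ",
                    "hydronephrosis."),
             "A female patient with entirely normal appearances.",
             "Entirely normal appearances throughout."),
    locale = "UK", stringsAsFactors = FALSE)
  m <- hydro_model()
  d <- c(hydro_dicts(), list(Gender = builtin_dictionary("Gender")))
  labels <- vector("list", 5)
  docs <- vector("list", 5)
  for (i in 1:5) {
    # match the Gender analytics dictionary alongside the model's own
    res <- classify_report(reports[i, ], m, d, return_doc = TRUE)
    extra <- match_terms(res$doc, d$Gender)
    res$doc$annotations <- rbind(res$doc$annotations, extra)
    res$doc$labels <- union(res$doc$labels, "Gender")
    labels[[i]] <- res$label
    docs[[i]] <- res$doc
  }
  labels <- do.call(rbind, labels)
  list(reports = reports, labels = labels, docs = docs,
       index = build_index(docs, labels, facets = "Gender"))
}

test_that("facets record mentions and document polarity separately", {
  fx <- fixture_index()
  idx <- fx$index
  # all three reports with a condition mention are under the Condition facet,
  # including the negated one
  expect_identical(idx$postings$Condition$hydronephrosis,
                   c("n1", "p1", "p2"))
  expect_identical(idx$postings$Presence$true, c("p1", "p2"))
  expect_identical(idx$postings$Presence$`false`, c("d1", "d2", "n1"))
  expect_identical(idx$postings$Gender$female, c("d1", "p2"))
})

test_that("combined facet search is a sorted conjunction", {
  fx <- fixture_index()
  expect_identical(search_index(fx$index, c(Condition = "hydronephrosis",
                                            Presence = "true")),
                   c("p1", "p2"))
  both <- search_index(fx$index, c(Condition = "hydronephrosis"))
  narrowed <- search_index(fx$index, c(Condition = "hydronephrosis",
                                       Gender = "female"))
  expect_true(all(narrowed %in% both))
  expect_identical(narrowed, "p2")
  # keyword filtering
  expect_identical(search_index(fx$index, c(Presence = "false"),
                                keyword = "pelviectasis"), "n1")
  # unknown facet value: empty, not an error
  expect_message(got <- search_index(fx$index, c(Condition = "unheard")),
                 "no postings")
  expect_identical(got, character(0))
  expect_error(search_index(fx$index), "at least one")
})

test_that("an empty corpus builds an empty index", {
  empty_labels <- classify_corpus(
    data.frame(id = character(), title = character(), text = character(),
               locale = character(), stringsAsFactors = FALSE),
    hydro_model(), hydro_dicts(), keep_docs = TRUE)
  idx <- build_index(empty_labels$docs, empty_labels$labels)
  expect_identical(length(idx$stored), 0L)
  expect_message(expect_identical(
    search_index(idx, c(Condition = "hydronephrosis")), character(0)))
})

test_that("duplicate report ids are rejected at build time", {
  fx <- fixture_index()
  labs <- rbind(fx$labels, fx$labels[1, ])
  expect_error(build_index(c(fx$docs, fx$docs[1]), labs), "duplicate")
})

test_that("snippets highlight the deciding mention with plain-text markup", {
  fx <- fixture_index()
  snip <- render_snippet(fx$index, "n1")
  expect_match(gsub("\\[\\[[^]]*\\]\\]", "", snip), "without frank",
               fixed = TRUE)
  expect_match(snip, "[[ConditionKeyword]]hydronephrosis[[/]]", fixed = TRUE)
  expect_match(snip, "[[NegationIndicator]]without[[/]]", fixed = TRUE)
  # a report with no matches renders its leading window without highlights
  plain <- render_snippet(fx$index, "d2")
  expect_match(plain, "^Entirely normal")
  expect_false(grepl("[[", plain, fixed = TRUE))
  expect_error(render_snippet(fx$index, "nope"), "unknown report id")
})

test_that("adjacent annotations yield disjoint highlights in offset order", {
  fx <- fixture_index()
  snip <- render_snippet(fx$index, "p2")
  open_at <- gregexpr("[[", snip, fixed = TRUE)[[1]]
  close_at <- gregexpr("[[/]]", snip, fixed = TRUE)[[1]]
  # every open is matched and highlights do not nest
  expect_identical(sum(open_at > 0) - sum(close_at > 0), sum(close_at > 0))
  stripped <- gsub("\\[\\[[^]]*\\]\\]", "", snip)
  expect_true(grepl("hydronephrosis", stripped))
})

test_that("the index round-trips through its JSON file format", {
  fx <- fixture_index()
  path <- withr::local_tempfile(fileext = ".json")
  write_facet_index(fx$index, path)
  back <- read_facet_index(path)
  expect_identical(back$postings, fx$index$postings)
  expect_identical(sort(names(back$stored)), sort(names(fx$index$stored)))
  expect_identical(search_index(back, c(Condition = "hydronephrosis",
                                        Presence = "true")),
                   c("p1", "p2"))
  expect_identical(render_snippet(back, "n1"), render_snippet(fx$index, "n1"))
})

test_that("search agrees with a linear-scan oracle on generated corpora", {
  set.seed(510)
  prof <- corpus_profile("hydronephrosis", "UK")
  cc <- generate_corpus(prof, 60, seed = 61)
  res <- classify_corpus(cc$reports, hydro_model(), hydro_dicts(),
                         keep_docs = TRUE)
  idx <- build_index(res$docs, res$labels)
  queries <- list(
    c(Condition = "hydronephrosis"),
    c(Presence = "true"),
    c(Presence = "false"),
    c(Condition = "hydronephrosis", Presence = "true"),
    c(Condition = "hydronephrosis", Presence = "false"))
  for (q in queries) {
    expect_identical(search_index(idx, q),
                     oracle_search(res$docs, res$labels, q))
    kw <- sample(c("hydronephrosis", "kidneys", "surveillance"), 1)
    expect_identical(search_index(idx, q, keyword = kw),
                     oracle_search(res$docs, res$labels, q, keyword = kw))
  }
  # adding a predicate never enlarges the result
  expect_lte(length(search_index(idx, queries[[4]])),
             length(search_index(idx, queries[[1]])))
})
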
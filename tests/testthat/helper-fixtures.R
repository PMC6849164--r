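# Shared fixtures, built in code.

# The three difficult hydronephrosis cases used throughout the tests.
table3_case1 <- "Reason: Evaluate for effusion; Admitting Diagnosis: HYDRONEPHROSIS"
table3_case2 <- paste("The right kidney is considerably lower in location than",
                      "the left with slight pelviectasis but without frank",
                      "hydronephrosis")
table3_case3 <- paste(
  "FINDINGS: Initial images raised the possibility of mild bilateral",
  "hydronephrosis; however, repeat imaging with a different probe and in",
  "different positions suggests that this is likely fat hypertrophy within",
  "the renal sinus bilaterally. IMPRESSION: No definite hydronephrosis.")

hydro_model <- function(...) {
  m <- builtin_condition_model("hydronephrosis")
  overrides <- list(...)
  for (k in names(overrides)) m[[k]] <- overrides[[k]]
  m
}

brain_model <- function(...) {
  m <- builtin_condition_model("brain_metastasis")
  overrides <- list(...)
  for (k in names(overrides)) m[[k]] <- overrides[[k]]
  m
}

hydro_dicts <- function() builtin_dictionaries(hydro_model())
brain_dicts <- function() builtin_dictionaries(brain_model())

# Random token text over a small closed vocabulary, with occasional
# punctuation so sentence boundaries appear. Uses the current RNG state.
random_text <- function(n_tokens, vocab) {
  words <- sample(vocab, n_tokens, replace = TRUE)
  out <- character()
  for (w in words) {
    out <- c(out, w)
    if (stats::runif(1) < 0.12) out <- c(out, ". ")
  }
  paste(out, collapse = " ")
}

# A random dictionary of 1-3 token terms drawn from the same vocabulary.
random_dictionary <- function(name, vocab, n_terms) {
  terms <- vapply(seq_len(n_terms), function(i) {
    paste(sample(vocab, sample(1:3, 1L), replace = TRUE), collapse = " ")
  }, character(1))
  rad_dictionary(name, unique(terms))
}

.test_vocab <- c("alpha", "bravo", "charlie", "delta", "echo", "foxtrot",
                 "golf", "hotel", "india", "juliet", "kilo", "lima")
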
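---
title: "Rule-based positive-incidence detection in radiology reports: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based positive-incidence detection in radiology reports: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radincidence)
```

## The task and the model

Radiology reports mention clinical conditions in many ways that are *not* a
current positive finding: the mention may be negated ("without frank
hydronephrosis"), the reason for the study ("Evaluate for ..."), part of the
clinical history ("Known ...", "Admitting Diagnosis: ..."), or a finding that
has since resolved. The task addressed here is **positive incidence**: label a
report positive only when the condition is identified as present now.

The approach is deliberately shallow and auditable. The design principle is:

> a condition mention is presumed a positive instance unless a
> negative-instance indicator applies within the same sentence.

Concretely, for each report:

1. **Annotate.** Dictionary terms are matched over normalized token sequences
   and become annotations: the condition keywords, plus four indicator
   dictionaries — negation (*no*, *not*, *without*, *no evidence of*),
   evaluation (*query*, *evaluate*, *assess*), clinical history (*history*,
   *admitted*, *known*, *previous*, ...), and resolution (*resolved*,
   *cleared*, *improved*, ...).
2. **Create condition mentions.** In *cohesive* mode (hydronephrosis) every
   condition-dictionary match becomes a `ConditionKeyword` annotation with
   `present = unknown`. In *paired* mode (brain metastasis) the keywords are
   non-contiguous — a brain-related word and a metastasis-indicating word —
   so a `ConditionKeyword` is created only when one member of each dictionary
   co-occurs **within one sentence**.
3. **Apply indicator rules.** For each indicator dictionary `D`, the
   sentence-scoped ordered rule "`D` ... `ConditionKeyword`" sets
   `present = false` on the mention. Rules run in declared order and a
   feature is only written while still `unknown`, so the first rule to set a
   feature wins; the final default rule sets `present = true` on anything
   untouched. Every mention therefore ends with `present` either true or
   false, never unknown.
4. **Decide the document label.** With the last-occurrence step enabled
   (the default), only the mention with maximal start offset decides:
   radiologists typically restate the conclusion in the impression, so this
   suppresses earlier hedged or historical mentions ("raised the possibility
   of ... IMPRESSION: No definite ..."). Without it, any `present = true`
   mention makes the report positive.

The package implements this as a small declarative rule engine
([rule_spec()], [apply_ruleset()]) rather than hard-coded logic, so the same
machinery expresses other sentence-scoped patterns — for example the
worked example of a cancer-location rule: a body-organ annotation and a
cancer annotation in either order, at most five tokens apart, within one
sentence.

## Parameters that matter

* **`max_gap`** (tokens, default `Inf`): bounds the tokens between the
  closest edges of consecutive rule elements (after sorting by position for
  unordered groups). The indicator rules leave it unbounded within the
  sentence; the cancer-location example uses 5.
* **`paired_max_gap`** (tokens, default `Inf`): the paired condition rule
  requires only sentence-level co-occurrence, because that is all the task
  needs; a bound can be set per model.
* **`use_last_occurrence`** (default `TRUE`): resolves modality and
  restatement by letting the final mention decide.
* **`recall_over_precision`** (default `FALSE`): disables the negation rule
  only. Hedged negations such as "without frank hydronephrosis" then count
  positive — appropriate when the goal is to surface every potentially
  positive case for quality assurance.
* **`use_ordered_post_indicator`** (default `FALSE`): also apply
  indicator-*after*-keyword rules. Off by default because the pre-positioned
  form is the dominant pattern in radiology prose and the post-positioned
  rule costs precision on constructions like "... hydronephrosis; no
  obstruction".
* **`title_filter`** (brain model: `{head, brain}`): brain-related words
  such as *parenchymal* or *lobe* are ambiguous across body parts; the study
  title disambiguates ("CT Head" can show brain parenchyma, "CT Abdomen"
  cannot). A report with no title always passes, so the filter never blocks
  bare-text use.

Dictionaries are shipped as editable plain-text data
(`system.file("extdata", "dictionaries", package = "radincidence")`), not
code: term lists are the part of such models that local deployments must
adapt. The UK/US variant table (tumour→tumor, oedema→edema, ...) is applied
at normalization time so one dictionary serves both locales. One shipped
term, the bare `?` used for queried findings, is documented as inert as a
pre-keyword indicator: the tokenizer treats `?` as terminal punctuation, so
it ends its sentence before the keyword.

## Tokenization, sentences, sections

The tokenizer is a deterministic scanner: alphanumeric runs (hyphenated
words kept whole) and single punctuation characters, with 0-based half-open
character offsets; concatenating token slices with the inter-token gaps
reproduces the text exactly. Sentence boundaries fall after `.`, `!`, `?`,
at newline runs, and **before** a section header keyword followed by `:`
(REASON, INDICATION, HISTORY, CLINICAL HISTORY, FINDINGS, IMPRESSION,
CONCLUSION). Semicolons and ordinary colons never split. The header rule is
placed *before* the keyword, not after the colon, so that a one-line string
like

```
Reason: Evaluate for effusion; Admitting Diagnosis: HYDRONEPHROSIS
```

remains a single scope — which is exactly what makes the evaluation and
history indicators govern the keyword and classify this report negative.
Paragraphs are not modelled; no rule needs them.

## What the synthetic generator emulates — and what it does not

Private clinical corpora cannot ship with a package, so every stage is
exercised on synthetic reports ([generate_corpus()]). The generator emulates
the corpus profiles the models target: a UK profile averaging 70 tokens per
report and a US profile averaging 206 (lengths drawn lognormal with
`sdlog = 0.35` around the mean — only means are known, and a right-skewed
positive length distribution is the natural choice), section layout
(Reason/Indication line, FINDINGS, IMPRESSION), UK/US spelling and the US
preference for *assess* as the indication verb, and one incidence pattern
per report drawn from a template mix: plain positive, negated, evaluation
header, history, resolution, modality-then-negated-impression, paired
co-occurrence (same or split sentences), and keyword-free distractors. The
pattern tag determines the gold label deterministically. Filler sentences
come from a closed vocabulary disjoint from every dictionary.

True pattern prevalences in real corpora are unknown; the default mix
(30% positive patterns, the remainder spread over the negative patterns)
is an arbitrary but fixed choice, documented here once. The
`adversarial_fraction` dial injects implicit negations ("The patient
denies ... and X was excluded ...") that the explicit-negation dictionaries
cannot see. Such reports are gold-negative but classified positive, so they
appear as false positives: with positive-pattern mass `p` and adversarial
fraction `q`, expected precision is `p/(p + q)` while recall stays 1.0 —
and the measured metrics match this analytic expectation within binomial
error. This is the package's dial-a-metric check that the evaluation
machinery measures exactly what the generator injects.

Passing these closed-loop tests shows the pipeline is *internally*
consistent: rules recover exactly the labels the templates encode. It does
**not** show performance on real reports, whose phrasing diversity,
misspellings, institution-specific acronyms, and genuinely ambiguous cases
the generator deliberately does not model. On real data the published
approach was validated by stratified manual review ([sample_for_review()]
implements that 50 + 50 label-blind protocol).

## Numerical and degenerate-input choices

* Offsets are 0-based half-open everywhere; token indices are 1-based R row
  indices internally.
* Empty text is legal and classifies negative; an empty dictionary is an
  error.
* Longest match wins within a dictionary; equal-length overlaps and matches
  from different dictionaries are all kept (labels are consumed
  independently).
* Equal-length tie for the last occurrence cannot arise (offsets are
  distinct); two created mentions sharing a start (paired mode) are ordered
  by span end, and only one carries `last_occurrence = true` — their
  `present` values agree by construction because indicator rules quantify
  over all of them.
* Rule creations are de-duplicated on (label, span): re-applying a rule set
  is idempotent.
* Determinism: the generator, sampler, and pipeline take explicit seeds,
  restore the caller's RNG state, and produce byte-identical outputs per
  seed.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
oracle-equivalence checks use 500 random instances per component (reports of
up to 50 tokens, dictionaries of up to 10 terms), the closed-loop and
adversarial checks use 1000-report corpora, and the generator calibration
uses 1000 UK and 300 US reports. These sizes give stable multinomial counts
(binomial standard errors of a percentage at n = 1000 are about 1.5 points)
while keeping a full run to a couple of minutes.

## Known limitations

* No stemming or misspelling correction; matching is exact over normalized
  tokens.
* No concept-level mapping (UMLS and similar are out of scope); acronym
  ambiguity is only addressed by the title heuristic.
* Cross-sentence reference is not modelled: "multiple lesions found" two
  sentences after "brain metastasis queried" will not pair, and tumour
  location across sentences ("two enhancing lesions ... in the left frontal
  lobe") is out of reach by design.
* Implicit negation ("patient denies ...") defeats the explicit negation
  dictionaries — this is the documented failure mode that the adversarial
  generator quantifies.
* Facet search is an exact conjunctive filter over an in-memory index
  persisted as JSON; there is no ranking and no external search server.
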
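# Cohesive-keyword incidence model: hydronephrosis keywords are specific and
# contiguous, so a single condition dictionary suffices.
condition: hydronephrosis
keyword_mode: cohesive
condition_dictionary: HydronephrosisKeyword
negative_dictionaries:
  - NegationIndicator
  - EvaluationIndicator
  - HistoryIndicator
  - ResolutionIndicator
use_ordered_post_indicator: false
use_last_occurrence: true
recall_over_precision: false
title_filter: ~
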
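# Paired-dictionary incidence model: brain-related and metastasis-indicating
# keywords are non-contiguous, so the condition mention is built at sentence
# level from their co-occurrence. The title filter skips studies that cannot
# image brain parenchyma (e.g. CT Abdomen).
condition: brain_metastasis
keyword_mode: paired
dict1: BrainKeyword
dict2: MetastasisKeyword
paired_max_gap: .inf
negative_dictionaries:
  - NegationIndicator
  - EvaluationIndicator
  - HistoryIndicator
  - ResolutionIndicator
use_ordered_post_indicator: false
use_last_occurrence: true
recall_over_precision: false
title_filter: [head, brain]
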
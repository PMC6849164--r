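# Evaluation / query indicators (pre-keyword, sentence scope).
query
queried
evaluate
evaluation
assess
assessment
?
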
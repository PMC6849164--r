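# Negation indicators: negation in radiology is very explicit.
no
not
without
no evidence of
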
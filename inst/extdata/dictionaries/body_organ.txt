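# Body-organ terms for the cancer-location example rule.
breast
lung
liver
brain
kidney
prostate
bone
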
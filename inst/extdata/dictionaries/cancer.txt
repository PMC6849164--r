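# Cancer keywords for the cancer-location example rule.
cancer
carcinoma
malignancy
metastasized
metastasis
tumour|tumor
tumor
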
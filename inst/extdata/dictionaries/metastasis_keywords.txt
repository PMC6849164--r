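# Dict2: metastasis-indicating keywords (generic terms; pair with Dict1).
metastasis
metastases
metastatic
mets
deposit
deposits
lesion
lesions
tumour|tumor
tumor
tumours|tumors
tumors
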
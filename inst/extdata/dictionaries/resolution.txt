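# Resolution indicators: resolved findings are not current incidence.
resolved
resolving
resolution
cleared
improved
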
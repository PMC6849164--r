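# Clinical-history indicators: historical mentions are excluded.
history
admitted
admitting
known
previous
previously
prior
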
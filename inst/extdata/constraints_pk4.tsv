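marker_a	relation	marker_b
PK4	ABOVE	M95
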
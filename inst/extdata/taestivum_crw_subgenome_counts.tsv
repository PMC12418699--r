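subgenome	count
AA	1424
BB	1206
DD	965
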
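superfamily	count
Gypsy	3111
Copia	141
unknown	344
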
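source	n_functional	n_total
cognate_sbc	54	75
agsc_lib	80	203
tbc_lib	49	196
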
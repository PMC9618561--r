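antigen	splenocytes	b_cells	igg_b_cells	selected	flow_through	viability_selected
A	304	67	19	0.13	18.3	94.5
B	301	70	22	0.15	20.0	95.3
C	285	75	25	0.72	23.7	96.7
D	304	79	27	0.88	26.4	95.5
E	294	83	24	0.21	23.1	94.7
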
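method	D1	D2	D3	D4	D5	D6
M1	90.79	59.14	92.62	81.77	89.47	94.91
M2	84.33	54.97	84.87	80.45	84.79	92.29
M3	85.48	54.83	71.08	78.88	84.40	93.14
M4	80.18	53.79	88.59	77.65	83.38	93.34
M5	72.18	49.33	80.56	78.63	62.49	85.51
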
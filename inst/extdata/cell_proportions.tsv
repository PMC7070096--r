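type	layer	proportion
PC	L23	0.450
ChC	L23	0.045
BPC	L23	0.015
DBC	L23	0.015
LBC	L23	0.045
MC	L23	0.030
PC	L5	0.300
ChC	L5	0.030
DBC	L5	0.011
LBC	L5	0.035
MC	L5	0.024
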
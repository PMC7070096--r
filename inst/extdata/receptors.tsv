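receptor	tau_on_ms	tau_off_ms	E_rev_mV
AMPA	0.5	2.0	0
NMDA	2.0	100.0	0
GABAA	0.5	8.0	-75
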
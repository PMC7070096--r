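pre_type	pre_layer	post_type	post_layer	p	g_ampa_nS	g_nmda_nS	g_gabaa_nS	delay_ms	U	tau_facil_ms	tau_rec_ms
PC	L23	PC	L23	0.12	2.10	0.18	0	1	NA	NA	NA
PC	L23	PC	L5	0.16	2.10	0.18	0	1	NA	NA	NA
PC	L5	PC	L5	0.12	2.10	0.18	0	1	NA	NA	NA
PC	L5	PC	L23	0.04	2.10	0.18	0	1	NA	NA	NA
PC	L23	IN	L23	0.20	1.20	0.08	0	1	NA	NA	NA
PC	L23	IN	L5	0.08	1.20	0.08	0	1	NA	NA	NA
PC	L5	IN	L5	0.20	1.20	0.08	0	1	NA	NA	NA
PC	L5	IN	L23	0.08	1.20	0.08	0	1	NA	NA	NA
ChC	L23	PC	L23	0.35	0	0	2.7	1	NA	NA	NA
ChC	L5	PC	L5	0.35	0	0	2.7	1	NA	NA	NA
BPC	*	PC	*	0.15	0	0	1.5	1	NA	NA	NA
BPC	*	IN	*	0.10	0	0	1.0	1	NA	NA	NA
DBC	*	PC	*	0.15	0	0	1.5	1	NA	NA	NA
DBC	*	IN	*	0.10	0	0	1.0	1	NA	NA	NA
LBC	L23	PC	L23	0.25	0	0	11.5	1	0.07	50	2500
LBC	L23	PC	L5	0.25	0	0	2.7	1	NA	NA	NA
LBC	L5	PC	L5	0.25	0	0	3.0	1	NA	NA	NA
LBC	L5	PC	L23	0.25	0	0	2.7	1	0.07	50	2500
LBC	*	IN	*	0.15	0	0	1.5	1	NA	NA	NA
MC	L23	PC	L23	0.20	0	0	18.0	1	0.07	50	2500
MC	L23	PC	L5	0.20	0	0	5.4	1	NA	NA	NA
MC	L5	PC	L5	0.20	0	0	6.0	1	NA	NA	NA
MC	L5	PC	L23	0.20	0	0	5.4	1	0.07	50	2500
MC	*	IN	*	0.10	0	0	1.0	1	NA	NA	NA
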
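type	layer	C_m_pF	g_L_nS	E_L_mV	V_th_mV	Delta_T_mV	tau_w_ms	a_nS	b_pA	V_r_mV	I_bg_pA	w_min_pA
PC	L23	150	14	-70	-48	2	200	0	-20	-58	250	-80
PC	L5	170	14	-70	-48	2	200	0	-20	-58	250	-80
ChC	L23	100	11	-65	-45	1	30	0	5	-60	200	-1e9
ChC	L5	100	11	-65	-45	1	30	0	5	-60	200	-1e9
BPC	L23	90	10	-65	-45	1.5	80	2	20	-60	200	-1e9
DBC	L23	90	10	-65	-45	1.5	80	2	20	-60	200	-1e9
DBC	L5	90	10	-65	-45	1.5	80	2	20	-60	200	-1e9
LBC	L23	150	14	-70	-48	2	200	0	-20	-58	200	-80
LBC	L5	170	14	-70	-48	2	200	0	-20	-58	200	-80
MC	L23	100	9	-65	-47	2	600	4	14	-60	200	-1e9
MC	L5	100	9	-65	-47	2	600	4	14	-60	200	-1e9
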
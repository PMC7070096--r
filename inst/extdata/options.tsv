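key	value
dt_ms	0.05
v_peak_mult	5
delay_default_ms	1.0
stp_U	0.25
stp_tau_facil_ms	500
stp_tau_rec_ms	200
stp_r1_complement	0
cross_column_scale	0.1
cross_column_scale_inh	1.0
stim_rate_hz	1000
stim_window_ms	20
stim_weight_nS	28
readout_ms	160
n_per_column	2000
vth_sd_mV	3.8
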
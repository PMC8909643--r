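mediator	outcome	a	a_lo	a_hi	step2_or	step2_lo	step2_hi	total_or	total_lo	total_hi	printed_pct
SBP	CHD	0.77	0.49	1.04	1.03	1.02	1.04	1.16	1.12	1.21	16
DBP	CHD	0.22	0.06	0.38	1.05	1.04	1.06	1.16	1.12	1.21	7
TG	CHD	0.08	0.02	0.14	1.22	1.13	1.32	1.16	1.12	1.21	10
SBP	MI	0.77	0.49	1.04	1.03	1.02	1.03	1.15	1.10	1.20	14
DBP	MI	0.22	0.06	0.38	1.05	1.04	1.06	1.15	1.10	1.20	7
TG	MI	0.08	0.02	0.14	1.22	1.12	1.33	1.15	1.10	1.20	11
SBP	stroke	0.77	0.49	1.04	1.03	1.03	1.04	1.10	1.06	1.13	26
DBP	stroke	0.22	0.06	0.38	1.04	1.04	1.05	1.10	1.06	1.13	10
TG	stroke	0.08	0.02	0.14	1.00	0.95	1.06	1.10	1.06	1.13	0.4
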
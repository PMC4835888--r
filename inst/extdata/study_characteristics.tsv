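study	n_cases	n_ga	n_nv	n_ga_nv	n_controls	n_total	age_cases_mean	age_cases_sd	age_controls_mean	age_controls_sd	pct_female_cases	pct_female_controls
AUS	633	137	496	0	404	1037	75.95	8.50	71.03	6.92	64.60	55.40
WUE	547	220	287	40	384	931	73.54	6.74	78.26	5.30	63.90	63.02
MUE/TUE	356	97	129	130	321	677	76.16	7.54	69.50	8.25	64.89	55.80
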
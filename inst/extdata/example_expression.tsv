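gene	log_fold_change	p_value	t1	t2
mir01_pos001	-0.739	0.25233	-0.806	-0.568
mir01_pos002	-0.588	0.39636	-0.54	-0.575
mir01_pos003	-1.4	0.10541	-1.199	-1.526
mir01_neg001	1.31	0.0026	1.357	1.504
mir01_neg002	1.395	0.00462	1.176	1.486
mir01_neg003	1.088	0.00084	0.995	1.116
mir02_pos001	-1.293	0.30066	-1.211	-1.203
mir02_pos002	0.058	0.06461	0.051	0.061
mir02_pos003	-1.304	0.24441	-1.284	-1.254
mir02_neg001	1.499	0.00493	1.676	1.199
mir02_neg002	1.352	0.00318	1.313	1.269
mir02_neg003	1.492	0.002	1.085	1.758
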
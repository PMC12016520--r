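experiment	treatment	regime	n_bio	temp_c	ph	rpm	o2	d2h_water	mu_mean	mu_sd	td_mean	td_sd	od_max_mean	od_max_sd
temperature	65	batch	5	65	3	200	air	-47.6	0.09	0.02	8.03	1.53	1.37	0.12
temperature	70	batch	5	70	3	200	air	-55.0	0.10	0.01	7.07	0.65	1.96	0.14
temperature	75	batch	5	75	3	200	air	-54.2	0.16	0.02	4.38	0.60	1.61	0.23
temperature	80	batch	5	80	3	200	air	-52.7	0.19	0.01	3.73	0.19	1.65	0.21
ph	2	batch	5	70	2	200	air	-59.8	0.12	0.01	5.75	0.43	0.71	0.04
ph	3	batch	5	70	3	200	air	-55.0	0.10	0.01	7.07	0.65	1.96	0.14
ph	4	batch	5	70	4	200	air	-60.9	0.10	0.01	6.63	0.41	0.49	0.03
aeration	50	batch	5	70	3	50	air	-47.6	0.02	0.00	32.75	1.50	0.22	0.01
aeration	125	batch	5	70	3	125	air	-46.3	0.08	0.00	8.82	0.51	0.73	0.01
aeration	300	batch	5	70	3	300	air	-46.9	0.07	0.00	9.26	0.25	0.63	0.02
o2	0.2%	fed-batch	3	70	3	200	0.2	-46.9	0.02	0.00	33.05	8.64	0.08	0.00
o2	0.5%	fed-batch	3	70	3	200	0.5	-55.6	0.05	0.02	14.17	4.54	0.10	0.00
o2	2%	fed-batch	3	70	3	200	2.0	-51.3	0.09	0.01	7.42	0.63	0.24	0.02
o2	20%	fed-batch	3	70	3	200	20	-51.0	0.34	0.21	2.58	1.36	0.32	0.04
edonor	7	chemostat	6	70	2.25	200	20	-59.7	0.14	0.00	7.00	0.09	0.84	0.10
edonor	21	chemostat	9	70	2.25	200	20	-59.5	0.05	0.00	21.00	0.45	0.88	0.03
edonor	44	chemostat	6	70	2.25	200	20	-50.1	0.02	0.00	44.30	5.68	1.12	0.04
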
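experiment	treatment	bp0	bp0_sd	bp1	bp1_sd	bp2	bp2_sd	bp3	bp3_sd	ring_index	ring_index_sd
temperature	65	0.06	0.00	0.15	0.01	0.76	0.00	0.03	0.00	1.77	0.01
temperature	70	0.12	0.04	0.26	0.03	0.61	0.07	0.01	0.00	1.52	0.15
temperature	75	0.06	0.01	0.13	0.01	0.60	0.02	0.21	0.02	1.97	0.07
temperature	80	0.07	0.01	0.14	0.00	0.46	0.01	0.33	0.01	2.04	0.02
ph	2	0.18	0.00	0.31	0.00	0.36	0.00	0.15	0.00	1.48	0.00
ph	3	0.12	0.04	0.26	0.03	0.61	0.07	0.01	0.00	1.52	0.15
ph	4	0.05	0.00	0.15	0.01	0.72	0.01	0.07	0.00	1.81	0.02
aeration	50	0.22	0.01	0.35	0.02	0.41	0.01	0.02	0.00	1.23	0.02
aeration	125	0.07	0.00	0.18	0.01	0.70	0.01	0.05	0.00	1.74	0.03
aeration	300	0.07	0.00	0.19	0.01	0.68	0.01	0.06	0.00	1.72	0.01
o2	0.2%	0.09	0.02	0.26	0.05	0.55	0.06	0.09	0.01	1.64	0.25
o2	0.5%	0.11	0.02	0.35	0.07	0.51	0.09	0.02	0.01	1.43	0.38
o2	2%	0.25	0.01	0.44	0.00	0.31	0.02	0.01	0.00	1.08	0.41
o2	20%	0.18	0.02	0.38	0.05	0.36	0.05	0.08	0.12	1.35	0.80
edonor	7	0.31	0.00	0.39	0.01	0.28	0.00	0.02	0.00	1.01	0.01
edonor	21	0.22	0.00	0.35	0.00	0.39	0.00	0.03	0.00	1.23	0.02
edonor	44	0.13	0.00	0.27	0.00	0.54	0.01	0.06	0.00	1.53	0.02
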
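experiment	treatment	moiety	d2h	d2h_sd	eps	eps_sd	ring_diff	ring_diff_sd
temperature	65	BP-0	-234	18	-195	19	NA	NA
temperature	65	BP-1	-232	5	-193	5	2	19
temperature	65	BP-2	-243	3	-205	3	-9	6
temperature	65	BP-3	NA	NA	NA	NA	NA	NA
temperature	65	weighted	-241	6	-203	5	-5	0
temperature	70	BP-0	-221	8	-175	9	NA	NA
temperature	70	BP-1	-225	5	-180	5	-5	10
temperature	70	BP-2	-225	3	-180	3	-2	4
temperature	70	BP-3	NA	NA	NA	NA	NA	NA
temperature	70	weighted	-225	5	-180	4	-3	0
temperature	75	BP-0	-262	4	-220	5	NA	NA
temperature	75	BP-1	-256	4	-214	5	6	7
temperature	75	BP-2	-268	5	-226	6	-8	4
temperature	75	BP-3	-268	4	-227	4	-3	3
temperature	75	weighted	-266	5	-224	5	-3	2
temperature	80	BP-0	-253	13	-211	13	NA	NA
temperature	80	BP-1	-248	6	-206	7	5	15
temperature	80	BP-2	-262	5	-221	5	-10	6
temperature	80	BP-3	-260	3	-219	3	-2	3
temperature	80	weighted	-259	5	-218	6	-4	3
ph	2	BP-0	-258	25	-211	27	NA	NA
ph	2	BP-1	-252	19	-205	20	6	34
ph	2	BP-2	-248	11	-200	11	5	14
ph	2	BP-3	-228	22	-179	24	15	11
ph	2	weighted	-248	22	-200	19	10	9
ph	3	BP-0	-221	8	-175	9	NA	NA
ph	3	BP-1	-225	5	-180	5	-5	10
ph	3	BP-2	-225	3	-180	3	-2	4
ph	3	BP-3	NA	NA	NA	NA	NA	NA
ph	3	weighted	-225	4	-180	4	-3	0
ph	4	BP-0	-249	9	-201	10	NA	NA
ph	4	BP-1	-251	6	-202	6	-1	12
ph	4	BP-2	-261	5	-214	6	-9	5
ph	4	BP-3	-257	6	-209	7	-1	4
ph	4	weighted	-259	5	-211	6	-4	3
aeration	50	BP-0	-230	3	-192	3	NA	NA
aeration	50	BP-1	-227	5	-189	5	3	6
aeration	50	BP-2	-232	4	-193	4	-3	4
aeration	50	BP-3	-222	34	-183	36	5	14
aeration	50	weighted	-230	6	-191	7	2	10
aeration	125	BP-0	-235	12	-198	12	NA	NA
aeration	125	BP-1	-231	7	-194	7	4	15
aeration	125	BP-2	-239	7	-202	7	-5	6
aeration	125	BP-3	-239	21	-202	22	-2	9
aeration	125	weighted	-237	9	-200	9	-2	7
aeration	300	BP-0	-238	6	-201	7	NA	NA
aeration	300	BP-1	-240	5	-202	5	-2	8
aeration	300	BP-2	-244	2	-207	2	-4	3
aeration	300	BP-3	-254	13	-217	13	-8	5
aeration	300	weighted	-243	4	-206	4	-5	4
o2	0.2%	BP-0	-244	2	-208	8	NA	NA
o2	0.2%	BP-1	-275	7	-239	3	-31	5
o2	0.2%	BP-2	-231	13	-193	17	20	3
o2	0.2%	BP-3	-231	9	-194	15	12	1
o2	0.2%	weighted	-248	9	-213	7	7	3
o2	0.5%	BP-0	-255	5	-211	5	NA	NA
o2	0.5%	BP-1	-237	4	-192	5	11	8
o2	0.5%	BP-2	-239	5	-194	6	5	4
o2	0.5%	BP-3	NA	NA	NA	NA	NA	NA
o2	0.5%	weighted	-244	4	-200	5	7	0
o2	2%	BP-0	-243	5	-202	6	NA	NA
o2	2%	BP-1	-242	2	-201	4	1	0
o2	2%	BP-2	-242	4	-200	5	1	0
o2	2%	BP-3	NA	NA	NA	NA	NA	NA
o2	2%	weighted	-242	5	-201	5	1	1
o2	20%	BP-0	-243	1	-202	1	NA	NA
o2	20%	BP-1	-243	4	-202	5	0	2
o2	20%	BP-2	-246	5	-205	5	-2	1
o2	20%	BP-3	NA	NA	NA	NA	NA	NA
o2	20%	weighted	-244	5	-203	6	-2	2
edonor	7	BP-0	-280	7	-234	7	NA	NA
edonor	7	BP-1	-276	4	-230	4	4	8
edonor	7	BP-2	-272	6	-226	5	4	4
edonor	7	BP-3	-253	17	-205	19	14	8
edonor	7	weighted	-276	6	-230	6	9	6
edonor	21	BP-0	-261	6	-214	6	NA	NA
edonor	21	BP-1	-261	5	-214	6	0	8
edonor	21	BP-2	-257	5	-210	5	3	4
edonor	21	BP-3	-237	18	-189	20	14	8
edonor	21	weighted	-259	5	-212	6	8	6
edonor	44	BP-0	-253	4	-214	5	NA	NA
edonor	44	BP-1	-246	6	-207	6	7	7
edonor	44	BP-2	-242	3	-202	3	5	4
edonor	44	BP-3	-239	5	-199	5	4	2
edonor	44	weighted	-244	4	-205	4	5	2
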
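system	runs	conserved	new_interface	unstable
1JTD	60	37	18	5
2YVJ	60	47	12	1
3PC8	60	50	10	0
3F1P	60	43	16	1
2VXT	42	28	11	3
3K75	60	53	6	1
4H03	60	49	11	0
4G6M	60	32	25	3
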
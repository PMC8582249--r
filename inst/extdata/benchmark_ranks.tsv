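system	n_poses	external_score	mean_bsa	mean_irmsd	mean_hbs	hbs_over_irmsd
1JTD	20	4	4	10	1	1
2YVJ	20	2	4	2	4	3
3PC8	20	1	8	1	3	1
3F1P	20	12	1	3	1	1
2VXT	14	4	1	3	1	1
3K75	20	8	15	1	15	6
4H03	20	6	5	3	6	2
4G6M	20	3	1	1	1	1
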
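chrom	length_mb	n_snps	density_printed	avg_distance_kb_printed
A01	115.95	703	6.06	164.94
A02	105.67	346	3.27	305.41
A03	110.12	427	3.88	257.90
A04	84.63	230	2.72	367.95
A05	108.86	604	5.55	180.24
A06	126.11	742	5.88	169.96
A07	96.73	622	6.43	155.51
A08	125.57	807	6.43	155.60
A09	83.56	463	5.54	180.48
A10	114.91	793	6.90	144.91
A11	119.36	644	5.40	185.34
A12	105.78	348	3.29	303.95
A13	108.61	552	5.08	196.75
D01	64.53	412	6.38	156.63
D02	71.14	504	7.08	141.14
D03	53.68	796	14.83	67.44
D04	56.27	242	4.30	232.52
D05	64.11	359	5.60	178.59
D06	66.01	562	8.51	117.46
D07	58.84	366	6.22	160.76
D08	68.68	493	7.18	139.30
D09	52.56	375	7.13	140.16
D10	65.68	599	9.12	109.65
D11	72.55	906	12.49	80.07
D12	62.68	351	5.60	178.57
D13	63.92	325	5.08	196.68
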
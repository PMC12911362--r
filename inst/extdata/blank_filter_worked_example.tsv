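feature_id	s1	s2	s3	s4	b1	b2
F01	1000	1100	900	1050	0	0
F02	900	950	880	920	2000	2100
F03	100	120	90	110	10	12
F04	100	95	105	100	150	160
F05	50	55	45	52	30	28
F06	10000	9500	10500	9800	5000	5200
F07	10	12	9	11	8	9
F08	5000	5200	4800	5100	6000	6100
F09	300	320	280	310	0	0
F10	20	25	15	22	40	45
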
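score	burden_class	min_prop	max_first_minute
1	C	0.10	10
2	C	0.10	NA
3	C	0.05	NA
4	C	0	NA
5	C_B23	0.30	NA
6	C_B23	0.15	NA
7	C_B23	0.05	NA
8	C_B23	0	NA
9	C_B23_B1	0.30	NA
10	C_B23_B1	0.15	NA
11	C_B23_B1	0.05	NA
12	C_B23_B1	0	NA
13	BELOW_A1	0	NA
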
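locality_id	inbreeding_coefficient
2	0.3983
3	0.1700
5	0.4223
6	0.3685
10	0.2181
11	0.4523
12	0.4434
13	0.3336
14	0.3167
15	0.3278
16	0.2971
18	0.3677
19	0.4026
20	0.3515
22	0.359
27	0.2939
29	0.353
30	0.3369
31	0.4309
39	0.3649
40	0.4267
41	0.3738
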
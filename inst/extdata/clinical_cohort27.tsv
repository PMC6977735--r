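pair_id	age_primary	age_recurrent	sex	localization	margin_primary	margin_recurrent	time_to_recurrence	dmr_count
1	64	68	Female	Upper leg	R1	R1	3.7	32854
2	78	79	Male	Retroperitoneal	R1	R2	1.9	2430
3	58	69	Female	Upper leg	R1	R1	10.6	4410
4	50	59	Male	Upper leg	Rx	R2	8.3	1061
5	62	67	Male	Axilla	R0	Rx	5.3	1191
6	31	39	Female	Upper leg	R1	R0	8.5	2732
8	60	61	Male	Lower leg	Rx	Rx	1.0	724
9	38	40	Female	Upper leg	R1	R1	2.1	675
10	68	69	Female	Mediastinum	R0	R1	1.3	1747
11	52	54	Female	Retroperitoneal	Rx	Rx	2.6	1028
13	50	58	Female	Retroperitoneal	R1	R1	8.1	3659
14	64	64	Male	Upper leg	R0	R1	0.6	636
15	55	57	Female	Retroperitoneal	R1	R1	2.0	1920
16	48	48	Male	Lower leg	R1	R1	0.4	473
17	70	70	Male	Esophagus	R2	R2	0.1	586
19	43	48	Male	Upper leg	R1	R1	4.7	7644
20	64	70	Male	Upper leg	R1	R1	6.5	21585
21	52	56	Male	Retroperitoneal	R0	R0	3.5	1481
22	59	63	Female	Retroperitoneal	Rx	R1	4.2	314
23	47	63	Male	Upper leg	R1	R0	16.6	1119
24	76	79	Female	Upper leg	R1	R0	3.0	372
25	49	53	Female	Upper leg	Rx	R1	3.9	482
26	50	53	Female	Retroperitoneal	Rx	Rx	2.1	2513
27	60	61	Male	Retroperitoneal	Rx	R1	1.5	1377
28	71	77	Female	Upper leg	R0	R1	6.1	1910
29	60	74	Male	Trunk	Rx	R1	13.8	2819
30	61	66	Female	Upper leg	R1	R2	4.6	294
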
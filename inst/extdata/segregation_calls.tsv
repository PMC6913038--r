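sire	HP_BTA5	HP_BTA14	HP_BTA18	NF_BTA8	NF_BTA11	NF_BTA22
1	1 vs. 2	NS	NS	NS	49 vs. 45	NS
2	1 vs. 3	NS	NS	NS	40 vs. 45	NS
3	1 vs. 4	NS	NS	NS	NS	NS
4	5 vs. 6	NS	NS	NS	40 vs. 44	NS
5	7 vs. 8	NS	NS	NS	52 vs. 53	NS
6	9 vs. 10	NS	NS	36 vs. 37	NS	NS
7	NS	11 vs. 12	NS	NS	NS	NS
8	NS	13 vs. 14	NS	30 vs. 32	50 vs. 51	NS
9	NS	15 vs. 14	NS	NS	NS	NS
10	NS	16 vs. 17	NS	NS	NS	NS
11	NS	18 vs. 19	22 vs. 23	38 vs. 39	NS	NS
12	NS	20 vs. 21	23 vs. 24	NS	NS	NS
13	NS	NS	25 vs. 26	NS	NS	NS
14	NS	NS	27 vs. 24	NS	NS	NS
15	NS	NS	28 vs. 29	NS	48 vs. 45	NS
16	NS	NS	NS	30 vs. 31	NS	NS
17	NS	NS	NS	33 vs. 34	NS	60 vs. 61
18	NS	NS	NS	35 vs. 34	NS	NS
19	NS	NS	NS	NS	40 vs. 41	NS
20	NS	NS	NS	NS	40 vs. 42	62 vs. 63
21	NS	NS	NS	NS	40 vs. 43	NS
22	NS	NS	NS	NS	46 vs. 45	59 vs. 58
23	NS	NS	NS	NS	47 vs. 45	NS
24	NS	NS	NS	NS	54 vs. 42	NS
25	NS	NS	NS	NS	55 vs. 41	NS
26	NS	NS	NS	NS	44 vs. 41	NS
27	NS	NS	NS	NS	NS	56 vs. 57
28	NS	NS	NS	NS	NS	64 vs. 65
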
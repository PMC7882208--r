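node_id	label	x_mm	y_mm	z_mm
1	node001	-9.4	10.4	59
2	node002	1.9	-26.4	57
3	node003	17	27	55
4	node004	-32.3	-6.9	53
5	node005	31.1	-24	51
6	node006	-10.5	47.4	49
7	node007	-20.1	-46.9	47
8	node008	43.5	19.3	45
9	node009	-45.1	22.6	43
10	node010	21.7	-56.2	41
11	node011	15.9	61.6	39
12	node012	-47.7	-33.6	37
13	node013	55.5	-14.8	35
14	node014	-33.6	58.1	33
15	node015	-7.7	-72.2	31
16	node016	46.9	48	29
17	node017	-62.5	3.1	27
18	node018	45.1	-54.5	25
19	node019	-3	78.4	23
20	node020	-42	-61.1	21
21	node021	65.8	10.8	19
22	node022	-55.1	46.6	17
23	node023	14.9	-80.3	15
24	node024	34	72	13
25	node025	-65.6	-25.4	11
26	node026	62.8	-35.2	9
27	node027	-26.8	77.9	7
28	node028	-23.6	-79.7	5
29	node029	61.9	39.5	3
30	node030	-67.7	21.7	1
31	node031	37.9	-71.5	-1
32	node032	11.8	83.7	-3
33	node033	-55.2	-51.9	-5
34	node034	69.3	-7	-7
35	node035	-47	61.7	-9
36	node036	0.3	-83.6	-11
37	node037	45.9	61.5	-13
38	node038	-67.5	-7.6	-15
39	node039	53.5	-49.3	-17
40	node040	-11.9	79.3	-19
41	node041	-34.9	-67.4	-21
42	node042	62.4	20.8	-23
43	node043	-56.6	35.3	-25
44	node044	21.7	-71.2	-27
45	node045	23.1	68.9	-29
46	node046	-54.2	-31.2	-31
47	node047	55.9	-20.9	-33
48	node048	-28.7	59.6	-35
49	node049	-11.6	-65.4	-37
50	node050	43.4	37.4	-39
51	node051	-50.7	7.7	-41
52	node052	31.6	-45.1	-43
53	node053	1.7	56.2	-45
54	node054	-30.5	-37.6	-47
55	node055	40.3	2.5	-49
56	node056	-28.4	28.5	-51
57	node057	4.5	-39.5	-53
58	node058	15.9	28	-55
59	node059	-21.3	-6	-57
60	node060	11.1	-7.6	-59
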
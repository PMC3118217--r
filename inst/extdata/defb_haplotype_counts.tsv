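locus	reads	counts	annotation	cn
DEFB4	51	17:34	3n	6
DEFB4	89	16:62:11	.	6
downstream	45	10:26:9	.	5
downstream	35	11:14:4:6	.	7
DEFB103	102	25:12:19:13:12:21	.	8
DEFB103	33	8:6:11:8	.	5
DEFB103	64	9:8:47	.	6
SPAG11	38	15:23	.	5
SPAG11	60	29:16:15	.	4
SPAG11	100	50:16:34	.	6
SPAG11	42	7:12:15:8	.	6
SPAG11	63	22:11:12:18	.	6
SPAG11	54	20:27:7	.	8
SPAG11	37	20:10:7	.	6
SPAG11	35	19:16	2n	6
SPAG11	48	14:21:13	.	7
SPAG11	30	4:21:5	.	7
SPAG11	32	8:14:10	.	7
SPAG11	48	7:22:19	.	7
SPAG11	48	9:20:6:13	.	5
SPAG11	62	13:18:13:7:11	.	8
SPAG11	34	6:13:15	.	6
SPAG11	33	12:21	3n	6
SPAG11	40	6:8:26	.	6
SPAG11	33	3:4:21:5	.	7
SPAG11	53	12:33:8	.	5
DEFB104	36	17:7:12	.	6
DEFB104	37	14:16:7	.	5
DEFB104	53	10:17:17:9	.	6
DEFB104	32	20:12	3n	6
DEFB104	30	13:10:7	.	6
DEFB104	30	14:6:6:4	.	6
DEFB104	86	63:26	.	4
DEFB104	62	6:8:21:27	.	8
DEFB104	65	13:23:15:14	.	5
DEFB104	31	6:6:6:5:8	.	6
DEFB104	38	10:10:5:3:10	.	8
DEFB104	29	6:7:16	.	5
DEFB104	31	9:14:8	.	7
DEFB104	33	6:27	.	6
DEFB106	100	32:12:18:38	.	6
DEFB106	77	21:13:31:12	.	7
DEFB106	30	8:22	4n	8
DEFB106	63	20:8:22:13	.	6
DEFB106	61	17:6:24:14	.	8
DEFB106	39	7:5:27	.	6
DEFB107	28	5:5:5:13	.	6
DEFB107	97	78:19	.	5
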
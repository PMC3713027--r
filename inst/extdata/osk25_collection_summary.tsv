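gil_id	input_arrays	outlier_arrays	edges	nodes	threshold	avg_degree	modules	status
G0001	22	0	NA	NA	NA	NA	NA	failed_rmt_no_threshold_found
G0002	81	0	19338	2890	0.91	13.38	569	ok
G0003	73	2	36346	3155	0.92	23.04	676	ok
G0004	14	NA	NA	NA	NA	NA	NA	too_few_arrays
G0005	26	0	14641	1991	0.97	14.71	290	ok
G0006	32	0	38331	1914	0.97	40.05	355	ok
G0007	90	0	12059	2806	0.91	8.60	370	ok
G0008	65	3	18383	3276	0.91	11.22	476	ok
G0009	25	0	3579	1366	0.99	5.24	173	ok
G0010	16	1	NA	NA	NA	NA	NA	failed_rmt_no_threshold_found
G0011	74	0	10411	1624	0.96	12.82	397	ok
G0012	40	0	29971	3622	0.93	16.55	522	ok
G0013	37	0	2366	896	0.98	5.28	150	ok
G0014	118	3	6738	1963	0.90	6.87	330	ok
G0015	21	0	9374	1034	0.98	18.13	256	ok
G0016	21	1	2358	1670	0.97	2.82	129	ok
G0017	24	0	8688	1607	0.96	10.81	194	ok
G0018	36	0	8434	1660	0.95	10.16	216	ok
G0019	19	1	4689	3022	0.97	3.10	234	ok
G0020	73	3	6268	2308	0.91	5.43	260	ok
G0021	231	2	227	204	0.98	2.23	24	ok
G0022	58	0	7516	2007	0.92	7.49	279	ok
G0023	54	3	34398	1596	0.94	43.11	302	ok
G0024	39	0	5880	2512	0.95	4.68	325	ok
G0025	57	0	2489	1167	0.98	4.27	135	ok
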
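Genes	Model	minus_lnL	np	LRT	Comparisons	p_value	omega_non_hypoxia	omega_terrestrial	omega_aquatic
CAT	1w	15735.439	86	NA	NA	NA	0.124	0.124	0.124
CAT	2w	15733.058	87	4.763	2w vs. 1w	0.029	0.118	0.147	0.147
CAT	3w	15732.816	88	0.484	3w vs. 2w	0.487	0.118	0.141	0.161
CAT	5w	15730.316	90	4.999	5w vs. 3w	0.082	0.118	0.103/0.162	0.179/0.125
SOD1	1w	5726.588	86	NA	NA	NA	0.261	0.261	0.261
SOD1	2w	5724.447	87	4.282	2w vs. 1w	0.039	0.281	0.198	0.198
SOD1	3w	5724.313	88	0.267	3w vs. 2w	0.605	0.282	0.186	0.218
SOD1	5w	5718.805	90	11.017	5w vs. 3w	0.004	0.280	0.079/0.274	0.291/0.129
SOD2	1w	5981.584	84	NA	NA	NA	0.115	0.115	0.115
SOD2	2w	5981.059	85	1.050	2w vs. 1w	0.305	0.110	0.134	0.134
SOD2	3w	5978.089	86	5.939	3w vs. 2w	0.015	0.111	0.102	0.243
SOD2	5w	5977.952	88	0.276	5w vs. 3w	0.871	0.111	0.112/0.097	0.261/0.202
SOD3	1w	9905.292	86	NA	NA	NA	0.129	0.129	0.129
SOD3	2w	9904.900	87	0.784	2w vs. 1w	0.376	0.134	0.119	0.119
SOD3	3w	9904.296	88	1.209	3w vs. 2w	0.272	0.134	0.110	0.141
SOD3	5w	9902.997	90	2.598	5w vs. 3w	0.273	0.133	0.093/0.124	0.160/0.094
GPX1	1w	6408.047	86	NA	NA	NA	0.073	0.073	0.073
GPX1	2w	6407.484	87	1.126	2w vs. 1w	0.289	0.070	0.084	0.084
GPX1	3w	6407.248	88	0.473	3w vs. 2w	0.491	0.070	0.089	0.070
GPX1	5w	6405.224	90	4.047	5w vs. 3w	0.132	0.070	0.088/0.088	0.044/0.146
GPX2	1w	4011.799	86	NA	NA	NA	0.062	0.062	0.062
GPX2	2w	4009.106	87	5.387	2w vs. 1w	0.020	0.053	0.087	0.087
GPX2	3w	4007.588	88	3.037	3w vs. 2w	0.081	0.053	0.072	0.135
GPX2	5w	4006.917	90	1.342	5w vs. 3w	0.511	0.053	0.059/0.079	0.162/0.086
GPX3	1w	6738.610	84	NA	NA	NA	0.132	0.132	0.132
GPX3	2w	6738.067	85	1.086	2w vs. 1w	0.297	0.127	0.149	0.149
GPX3	3w	6733.463	86	9.207	3w vs. 2w	0.002	0.128	0.110	0.250
GPX3	5w	6730.568	88	5.790	5w vs. 3w	0.055	0.128	0.138/0.088	0.333/0.129
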
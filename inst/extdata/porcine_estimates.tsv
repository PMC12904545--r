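eyeball	meas	dcr_min	dcr_mu_s	dcr_g	drms_min	drms_mu_s	drms_g	dkl_min	dkl_mu_s	dkl_g	mu_s_hat	g_hat
1	1	0.0200	0.18	0.85	0.0403	0.10	0.91	0.0027	0.10	0.91	0.127	0.890
1	2	0.0167	0.18	0.85	0.0380	0.14	0.93	0.0023	0.10	0.91	0.140	0.897
1	3	0.0151	0.18	0.85	0.0379	0.14	0.93	0.0023	0.10	0.91	0.140	0.897
2	1	0.0437	0.18	0.85	0.0609	0.18	0.85	0.0078	0.19	0.89	0.183	0.863
2	2	0.0407	0.18	0.85	0.0626	0.18	0.85	0.0082	0.19	0.89	0.183	0.863
2	3	0.0439	0.18	0.85	0.0605	0.18	0.85	0.0077	0.19	0.89	0.183	0.863
3	1	0.0076	0.18	0.85	0.0314	0.10	0.91	0.0022	0.12	0.92	0.133	0.893
3	2	0.0194	0.18	0.85	0.0346	0.17	0.92	0.0024	0.12	0.92	0.157	0.897
3	3	0.0177	0.18	0.85	0.0360	0.17	0.92	0.0025	0.12	0.92	0.157	0.897
4	1	0.0264	0.18	0.85	0.0649	0.10	0.91	0.0080	0.10	0.91	0.127	0.890
4	2	0.0275	0.18	0.85	0.0668	0.10	0.91	0.0081	0.10	0.91	0.127	0.890
4	3	0.0231	0.18	0.85	0.0633	0.10	0.91	0.0071	0.10	0.91	0.127	0.890
5	1	0.0005	0.10	0.96	0.0349	0.10	0.91	0.0044	0.14	0.97	0.113	0.947
5	2	0.0000	0.12	0.95	0.0353	0.10	0.91	0.0043	0.14	0.97	0.120	0.943
5	3	0.0001	0.12	0.97	0.0322	0.10	0.91	0.0040	0.14	0.97	0.120	0.950
6	1	0.0431	0.18	0.85	0.0488	0.18	0.85	0.0040	0.17	0.92	0.177	0.873
6	2	0.0349	0.18	0.85	0.0434	0.18	0.85	0.0032	0.17	0.92	0.177	0.873
6	3	0.0386	0.18	0.85	0.0461	0.18	0.85	0.0037	0.17	0.92	0.177	0.873
7	1	0.0256	0.18	0.85	0.0419	0.14	0.93	0.0030	0.12	0.92	0.147	0.900
7	2	0.0192	0.18	0.85	0.0398	0.17	0.92	0.0032	0.12	0.92	0.157	0.897
7	3	0.0189	0.18	0.85	0.0377	0.10	0.91	0.0027	0.12	0.92	0.133	0.893
8	1	0.0455	0.18	0.85	0.0577	0.18	0.85	0.0054	0.12	0.92	0.160	0.873
8	2	0.0467	0.18	0.85	0.0565	0.18	0.85	0.0051	0.12	0.92	0.160	0.873
8	3	0.0453	0.18	0.85	0.0545	0.18	0.85	0.0051	0.12	0.92	0.160	0.873
9	1	0.0409	0.18	0.85	0.0572	0.14	0.93	0.0054	0.12	0.92	0.147	0.900
9	2	0.0413	0.18	0.85	0.0577	0.14	0.93	0.0054	0.12	0.92	0.147	0.900
9	3	0.0352	0.18	0.85	0.0528	0.14	0.93	0.0047	0.12	0.92	0.147	0.900
10	1	0.0140	0.18	0.85	0.0405	0.10	0.91	0.0034	0.12	0.92	0.133	0.893
10	2	0.0147	0.18	0.85	0.0416	0.10	0.91	0.0032	0.12	0.92	0.133	0.893
10	3	0.0156	0.18	0.85	0.0438	0.10	0.91	0.0034	0.12	0.92	0.133	0.893
11	1	0.0034	0.18	0.85	0.0299	0.10	0.91	0.0021	0.12	0.92	0.133	0.893
11	2	0.0021	0.18	0.85	0.0294	0.10	0.91	0.0023	0.12	0.92	0.133	0.893
11	3	0.0019	0.18	0.85	0.0254	0.10	0.91	0.0018	0.12	0.92	0.143	0.893
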
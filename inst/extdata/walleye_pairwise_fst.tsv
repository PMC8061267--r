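pop	1	2	3	4	5	6	7	8	9	10	11	12	13	14	15	16	17	18	19	20	21	22	23
1	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
2	0.039	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
3	0.041	0.019	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
4	0.064	0.054	0.037	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
5	0.025	0.016	0.016	0.029	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
6	0.037	0.030	0.024	0.025	0.005	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
7	0.037	0.033	0.024	0.025	0.009	0	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
8	0.042	0.040	0.029	0.033	0.016	0.010	0.009	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
9	0.074	0.075	0.064	0.067	0.047	0.045	0.044	0.055	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
10	0.042	0.035	0.023	0.019	0.010	0	0.003	0.009	0.047	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
11	0.038	0.027	0.017	0.024	0.009	0.003	0.005	0.008	0.050	0.003	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
12	0.037	0.033	0.020	0.031	0.016	0.009	0.011	0.008	0.057	0.009	0.004	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
13	0.071	0.075	0.059	0.079	0.064	0.063	0.061	0.049	0.105	0.062	0.040	0.035	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
14	0.047	0.047	0.030	0.038	0.019	0.005	0.009	0.008	0.059	0.009	0.007	0.006	0.046	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
15	0.065	0.051	0.041	0.071	0.047	0.053	0.053	0.056	0.096	0.054	0.047	0.045	0.082	0.059	NA	NA	NA	NA	NA	NA	NA	NA	NA
16	0.112	0.112	0.091	0.111	0.095	0.094	0.094	0.093	0.140	0.096	0.089	0.082	0.115	0.098	0.070	NA	NA	NA	NA	NA	NA	NA	NA
17	0.060	0.054	0.037	0.061	0.043	0.044	0.044	0.042	0.089	0.044	0.036	0.030	0.063	0.044	0.043	0.053	NA	NA	NA	NA	NA	NA	NA
18	0.055	0.061	0.036	0.055	0.039	0.035	0.036	0.035	0.084	0.037	0.032	0.025	0.057	0.043	0.048	0.068	0.025	NA	NA	NA	NA	NA	NA
19	0.094	0.098	0.076	0.096	0.078	0.077	0.077	0.076	0.122	0.078	0.073	0.066	0.098	0.083	0.082	0.097	0.060	0.050	NA	NA	NA	NA	NA
20	0.080	0.080	0.061	0.081	0.064	0.064	0.062	0.060	0.109	0.064	0.057	0.049	0.082	0.064	0.058	0.062	0.038	0.024	0.057	NA	NA	NA	NA
21	0.081	0.087	0.061	0.083	0.065	0.064	0.064	0.063	0.111	0.066	0.061	0.052	0.085	0.072	0.054	0.049	0.039	0.042	0.070	0.032	NA	NA	NA
22	0.067	0.069	0.049	0.069	0.051	0.050	0.050	0.048	0.096	0.050	0.044	0.037	0.070	0.052	0.053	0.065	0.030	0.019	0.053	0.021	0.030	NA	NA
23	0.103	0.104	0.084	0.105	0.088	0.088	0.088	0.087	0.133	0.089	0.083	0.076	0.108	0.093	0.076	0.068	0.064	0.068	0.097	0.071	0.055	0.064	NA
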
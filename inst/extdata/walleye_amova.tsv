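analysis	stratum	df	SSQ	Var
All	Among groups	1	39936.91	54.08
All	Among populations within groups	21	137207.96	67.26
All	Within populations	1655	2656558.49	1605.17
Wisconsin	Among groups	4	33994.29	10.51
Wisconsin	Among populations within groups	10	63073.48	55.18
Wisconsin	Within populations	1241	2069472.47	1667.58
Minnesota	Among groups	1	7049.11	7.05
Minnesota	Among populations within groups	6	33091.07	78.32
Minnesota	Within populations	414	587086.02	1418.08
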
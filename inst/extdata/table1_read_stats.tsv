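sample	treatment	replicate	total_reads	mapped_reads	unmapped_reads	pct_rrna	pct_mrna	pct_intergenic
Bt-totRNA	totRNA	1	4334132	41390060	1944072	99.63	0.29	0.08
Bt-totRNA	totRNA	2	3756060	36228341	1367719	99.95	0.03	0.02
Bt-Mex	Mex	1	26092578	24866950	1225628	96.57	2.82	0.61
Bt-Mex	Mex	2	29736910	28271413	1465497	99.06	0.49	0.45
Bt-Ov	Ov	1	13507220	10279802	3227418	52.48	41.15	6.37
Bt-Ov	Ov	2	15321918	11899910	3422008	70.13	24.51	5.37
Bt-Mex-Ov	Mex-Ov	1	10377152	7970400	2406752	62.57	30.04	7.39
Bt-Mex-Ov	Mex-Ov	2	7905258	6382124	1523134	45.73	46.11	8.16
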
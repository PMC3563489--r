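treatment	observed_reads	cds_above_dth	fraction_covered
totRNA	40000000	573	0.10
Mex	28000000	2284	0.50
Ov	14000000	5000	0.90
Mex-Ov	10000000	5000	1.00
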
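symbol	shells	occ_s	occ_p	mass
X	s	1	0	2.0
Y	s	1	0	3.0
Z	sp	2	2	12.0
H	s	1	0	1.008
C	sp	2	2	12.011
N	sp	2	3	14.007
O	sp	2	4	15.999
P	sp	2	3	30.973762
S	sp	2	4	32.06
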
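gene	s1	s2	s3	s4	s5	s6	s7	s8	s9	s10
KEEP1	10	10	10	10	10	10	10	10	20	20
KEEP2	15	15	15	15	15	15	15	15	15	15
KEEP3	12	12	12	12	12	12	12	12	12	4
DROP1	19	19	19	19	19	19	19	9	9	9
DROP2	500	0	0	0	0	0	0	0	0	0
DROP3	10	10	10	10	10	10	10	10	0	0
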
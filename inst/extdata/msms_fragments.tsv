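id	sequence	mz	z	flank_n	flank_c
21-22/a-b_1	IKLCLKI	444.36	2	K	-
21-22/a-b_2	IFECVFSCDIEK	773.98	2	-	E
21-22/a-b_3	IFECVFSCDIEKEGKPCKPK	618.64	4	-	G
21-22/c_1	CVFSCDXEK	579.10	2	-	-
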
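superfamily	canonical	n_cys	len_min	len_max	connectivity	free_cys	notes
SF1	C-C-CC-C	5	54	54	2-3;4-5	1
SF2	C-C-C-CC-C	6	48	48	1-4;2-5;3-6
SF3	C-C-CC-C-C-C	7	43	84	2-5;3-6;4-7	1
SF4	C-C-CC-C-C-C-C	8	44	74	1-8;2-3;4-5;6-7		alternative connectivity 1-7;2-8;3-6;4-5
SF5	C-C-C-CC-C-C-C	8	61	65	1-6;2-7;3-4;5-8
SF6	C-C-C-C-CC-C-C	8	43	71	1-6;2-7;3-5;4-8		WAP four-disulfide core domain
SF7	C-C-C-C-C-CC-C	8	76	80	1-5;2-6;3-7;4-8		SVWC domain
SF8	C-C-CC-C-C-C-C-C-C	10	67	88	1-6;2-4;3-5;7-10;8-9		alternative connectivity 1-3;2-4;5-6;7-8;9-10; astakine-like members
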
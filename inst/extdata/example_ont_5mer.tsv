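kmer	level_mean	level_stdv	weight
AAAAA	108.90	2.68	1.0
AAAAC	96.38	2.84	1.0
AAACA	91.28	2.27	1.0
AAAUA	103.52	2.45	1.0
GGACT	123.83	3.01	1.0
TTTTT	88.78	1.91	1.0
CCCCC	69.24	2.12	1.0
GGGGG	110.51	2.65	1.0
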
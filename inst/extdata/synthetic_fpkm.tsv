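gene_id	seed	endosperm	leaf	root
SYNGENE_chr4_00301	14.2	22.8	0.3	0.1
SYNGENE_chr4_00302	8.7	31.5	2.1	0.4
SYNGENE_chr4_00303	1.0	0.9	5.2	0.2
SYNGENE_chr4_00304	3.4	1.8	0.1	0.0
SYNGENE_chr4_00305	0.0	0.0	0.0	0.0
SYNGENE_chr4_00306	0.2	0.4	0.8	0.6
SYNGENE_chr2_00131	2.6	0.7	1.4	1.9
SYNGENE_chr2_00132	0.1	0.2	7.3	4.4
SYNGENE_chr2_00133	0.0	0.1	0.0	0.0
SYNGENE_chr2_00134	0.9	0.8	3.1	2.0
SYNGENE_chr10_00451	5.8	2.2	1.1	0.9
SYNGENE_chr10_00452	0.4	1.2	0.6	2.8
SYNGENE_chr10_00453	45.0	51.3	60.2	38.9
SYNGENE_chr10_00454	0.0	0.0	0.2	0.0
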
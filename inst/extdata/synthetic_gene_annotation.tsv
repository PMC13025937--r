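gene_id	description
SYNGENE_chr4_00301	FGGY carbohydrate kinase family protein
SYNGENE_chr4_00302	sucrose synthase 2
SYNGENE_chr4_00303	beta-amylase, chloroplastic
SYNGENE_chr4_00304	glycosyl hydrolase family 32, cell wall invertase
SYNGENE_chr4_00305	unknown protein
SYNGENE_chr4_00306	pentatricopeptide repeat-containing protein
SYNGENE_chr2_00131	hexokinase-like protein
SYNGENE_chr2_00132	cytochrome P450 family protein
SYNGENE_chr2_00133	unknown protein
SYNGENE_chr2_00134	MYB-family transcription factor
SYNGENE_chr10_00451	UDP-glycosyltransferase
SYNGENE_chr10_00452	leucine-rich repeat receptor-like kinase
SYNGENE_chr10_00453	ribosomal protein L7
SYNGENE_chr10_00454	unknown protein
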
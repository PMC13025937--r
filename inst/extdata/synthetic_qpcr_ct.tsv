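gene	line_class	ct_target	ct_reference
SYNGENE_chr4_00301	low	24.1	25.0
SYNGENE_chr4_00301	low	24.3	25.1
SYNGENE_chr4_00301	low	24.0	24.9
SYNGENE_chr4_00301	high	27.2	25.0
SYNGENE_chr4_00301	high	27.5	25.2
SYNGENE_chr4_00301	high	27.1	24.8
SYNGENE_chr4_00302	low	26.0	25.0
SYNGENE_chr4_00302	low	26.2	25.1
SYNGENE_chr4_00302	high	26.1	25.0
SYNGENE_chr4_00302	high	26.3	25.2
SYNGENE_chr4_00304	low	28.9	25.0
SYNGENE_chr4_00304	low	29.1	25.1
SYNGENE_chr4_00304	high	28.8	24.9
SYNGENE_chr4_00304	high	29.0	25.0
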
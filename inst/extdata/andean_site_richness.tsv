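site	n_sequences	observed_otus	chao1
P1	24214	11241	29216
P2	41075	15775	39579
P3	25988	10437	25608
pooled	91277	20463	61301
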
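gene	cds_length	role
APC	8532	suppressor
KRAS	567	oncogene
TP53	1182	suppressor
PIK3CA	3207	oncogene
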
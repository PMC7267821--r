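gene	Ha	Hd	Hi	Hb	Him
APC	0.6	0	0	0	0
KRAS	0	0.7	0	0	0.3
TP53	0.4	0.3	0	0	0
PIK3CA	0	0	0	0	0.7
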
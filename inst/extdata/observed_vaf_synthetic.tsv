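gene	vaf
APC	0.433556668210234
KRAS	0.457209423477657
TP53	0.0545482171799028
PIK3CA	0.0279650960870572
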
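name	recognition	cut_offset
BamHI	GGATCC	1
KpnI	GGTACC	5
AflII	CTTAAG	1
EcoRI	GAATTC	1
EcoRV	GATATC	3
HpaI	GTTAAC	3
MluI	ACGCGT	1
NheI	GCTAGC	1
SpeI	ACTAGT	1
XhoI	CTCGAG	1
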
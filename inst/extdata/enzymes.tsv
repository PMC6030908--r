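name	site
EcoRI	GAATTC
BamHI	GGATCC
HindIII	AAGCTT
NotI	GCGGCCGC
XhoI	CTCGAG
SalI	GTCGAC
PstI	CTGCAG
SmaI	CCCGGG
KpnI	GGTACC
SacI	GAGCTC
XbaI	TCTAGA
NcoI	CCATGG
NdeI	CATATG
SpeI	ACTAGT
BglII	AGATCT
EcoRV	GATATC
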
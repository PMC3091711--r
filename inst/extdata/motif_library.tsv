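name	category	consensus
MBS	drought-MBS	CAACTG
MYB-core	Myb-binding	CNGTTR
MRE	Myb-binding	AACCTAA
ABRE	ABA-responsive	ACGTG
CGTCA-motif	MeJA-responsive	CGTCA
TGACG-motif	MeJA-responsive	TGACG
G-box	light-responsive	CACGTG
Box4	light-responsive	ATTAAT
GT1-motif	light-responsive	GGTTAA
HSE	heat-stress	AAAAAATTTC
TATA-box	other	TATAAA
CAAT-box	other	CCAAT
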
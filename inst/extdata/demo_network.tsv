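source	target	interaction	source_type	target_type
SMAD2	JUN	regulates	TF	gene
SMAD3	JUN	regulates	TF	gene
SMAD2	SERPINE1	regulates	TF	gene
JUN	MMP9	regulates	TF	gene
FOS	MMP9	regulates	TF	gene
E2F1	CCNE1	regulates	TF	gene
E2F1	CDC6	regulates	TF	gene
RB1	E2F1	regulates	gene	TF
mir-21	SMAD3	represses	miRNA	TF
mir-21	RB1	represses	miRNA	gene
AR	JUN	regulates	TF	gene
AR	SERPINE1	regulates	TF	gene
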
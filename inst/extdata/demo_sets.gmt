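setSMAD23	TGF-beta/SMAD2-3 signalling (synthetic demo set)	SMAD2	SMAD3	TGFBR1	SERPINE1	JUN
setAP1	AP-1 complex targets (synthetic demo set)	JUN	FOS	ATF2	MMP9
setE2F	E2F/Rb cell-cycle targets (synthetic demo set)	E2F1	RB1	CCNE1	CDC6	MYBL2
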
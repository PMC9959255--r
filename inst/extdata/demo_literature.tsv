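node	count
SMAD2	310
SMAD3	290
JUN	510
FOS	420
E2F1	150
RB1	260
AR	12
mir-21	85
SERPINE1	96
MMP9	340
CCNE1	40
CDC6	18
ATF2	77
MYBL2	9
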
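; heme (HEME): 19 beads, net charge -2 (deprotonated propionates)
; united-atom table is a synthetic formula-accurate reconstruction;
; bead graph totals (beads/bonds/angles/impropers, charges) are authoritative.
[molecule] HEME -2
[atoms]
FE FE 55.845 26
NA N 14.007 7
C1A C 12.011 6
C2A C 12.011 6
C3A C 12.011 6
C4A C 12.011 6
NB N 14.007 7
C1B C 12.011 6
C2B C 12.011 6
C3B C 13.019 7
C4B C 12.011 6
NC N 14.007 7
C1C C 12.011 6
C2C C 12.011 6
C3C C 12.011 6
C4C C 12.011 6
ND N 14.007 7
C1D C 12.011 6
C2D C 12.011 6
C3D C 13.019 7
C4D C 12.011 6
CHA C 13.019 7
CHB C 13.019 7
CHC C 13.019 7
CHD C 13.019 7
CV1 C 13.019 7
CV2 C 14.027 8
CM1 C 15.035 9
CV3 C 13.019 7
CV4 C 14.027 8
CM2 C 15.035 9
CM3 C 15.035 9
CM4 C 15.035 9
CP1 C 14.027 8
CP2 C 14.027 8
CP3 C 12.011 6
OP1 O 15.999 8
OP2 O 15.999 8
CP4 C 14.027 8
CP5 C 14.027 8
CP6 C 12.011 6
OP3 O 15.999 8
OP4 O 15.999 8
[bead] FE1 SQ3p 0.40 : FE
[bead] NA1 TN6q -0.10 : NA C1A C4A
[bead] NB1 TN6q -0.10 : NB C1B C4B
[bead] NC1 TN6q -0.10 : NC C1C C4C
[bead] ND1 TN6q -0.10 : ND C1D C4D
[bead] TAB1 TC5 0.00 : C3A CHA
[bead] TAB2 TC5 0.00 : CHA C2B
[bead] TBC1 TC5 0.00 : C3B CHB
[bead] TBC2 TC5 0.00 : CHB C2C
[bead] TCD1 TC5 0.00 : C3C CHC
[bead] TCD2 TC5 0.00 : CHC C2D
[bead] TDA1 TC5 0.00 : C3D CHD
[bead] TDA2 TC5 0.00 : CHD C2A
[bead] SV1 SC5 0.00 : CV1 CV2 CM1
[bead] SV2 SC5 0.00 : CV3 CV4 CM2
[bead] TM1 TC5 0.00 : CM3
[bead] TM2 TC5 0.00 : CM4
[bead] PRA Q5n -1.00 : CP1 CP2 CP3 OP1 OP2
[bead] PRB Q5n -1.00 : CP4 CP5 CP6 OP3 OP4
[bonds]
NA1 TAB1
TAB1 TAB2
TAB2 NB1
NB1 TBC1
TBC1 TBC2
TBC2 NC1
NC1 TCD1
TCD1 TCD2
TCD2 ND1
ND1 TDA1
TDA1 TDA2
TDA2 NA1
FE1 NA1
FE1 NB1
FE1 NC1
FE1 ND1
NA1 NB1
NB1 NC1
NC1 ND1
ND1 NA1
NA1 NC1
NB1 ND1
FE1 TAB1
FE1 TAB2
FE1 TBC1
FE1 TBC2
FE1 TCD1
FE1 TCD2
FE1 TDA1
FE1 TDA2
SV1 TAB2
SV2 TCD2
TM1 TBC2
TM2 TDA2
PRA TCD1
PRB TDA1
[angles]
NA1 TAB1 TAB2
TAB1 TAB2 NB1
TAB2 NB1 TBC1
NB1 TBC1 TBC2
TBC1 TBC2 NC1
TBC2 NC1 TCD1
NC1 TCD1 TCD2
TCD1 TCD2 ND1
TCD2 ND1 TDA1
ND1 TDA1 TDA2
TDA1 TDA2 NA1
TDA2 NA1 TAB1
TAB1 TAB2 SV1
TCD1 TCD2 SV2
TBC1 TBC2 TM1
TDA1 TDA2 TM2
NC1 TCD1 PRA
ND1 TDA1 PRB
[impropers]
NA1 TAB1 TAB2 NB1
NB1 TBC1 TBC2 NC1
NC1 TCD1 TCD2 ND1
ND1 TDA1 TDA2 NA1
FE1 NA1 NB1 NC1
FE1 NB1 NC1 ND1
FE1 NC1 ND1 NA1
FE1 ND1 NA1 NB1
TAB1 TAB2 TBC1 TBC2
TBC1 TBC2 TCD1 TCD2
TCD1 TCD2 TDA1 TDA2
TDA1 TDA2 TAB1 TAB2
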
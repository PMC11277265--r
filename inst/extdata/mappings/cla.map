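; chlorophyll A (CLA): 23 beads, 44 bonds, 22 angles, 15 impropers; CHA-CHD doubly mapped
; united-atom table is a synthetic formula-accurate reconstruction;
; bead graph totals (beads/bonds/angles/impropers, charges) are authoritative.
[molecule] CLA 0
[atoms]
MG MG 24.305 12
NA N 14.007 7
C1A C 12.011 6
C2A C 12.011 6
C3A C 12.011 6
C4A C 12.011 6
NB N 14.007 7
C1B C 12.011 6
C2B C 12.011 6
C3B C 12.011 6
C4B C 12.011 6
NC N 14.007 7
C1C C 12.011 6
C2C C 12.011 6
C3C C 12.011 6
C4C C 12.011 6
ND N 14.007 7
C1D C 12.011 6
C2D C 12.011 6
C3D C 12.011 6
C4D C 12.011 6
CHA C 13.019 7
CHB C 13.019 7
CHC C 13.019 7
CHD C 13.019 7
CE1 C 12.011 6
CE2 C 13.019 7
CE3 C 14.027 8
OE1 O 15.999 8
CM3 C 15.035 9
CM4 C 15.035 9
CV1 C 13.019 7
CV2 C 14.027 8
CM1 C 15.035 9
CT1 C 14.027 8
CT2 C 15.035 9
CM2 C 15.035 9
CAA C 12.011 6
OAA O 15.999 8
OAB O 15.999 8
CAB C 15.035 9
CBA C 12.011 6
OBA O 15.999 8
OBB O 15.999 8
CBB C 15.035 9
PH1 C 14.027 8
PH2 C 13.019 7
PH3 C 14.027 8
PH4 C 14.027 8
PH5 C 14.027 8
PH6 C 13.019 7
PH7 C 14.027 8
PH8 C 14.027 8
PH9 C 14.027 8
PH10 C 15.035 9
PH11 C 13.019 7
PH12 C 14.027 8
PH13 C 14.027 8
PH14 C 14.027 8
PH15 C 15.035 9
PH16 C 13.019 7
PH17 C 14.027 8
PH18 C 14.027 8
PH19 C 15.035 9
PH20 C 14.027 8
[bead] MGB TQ3p 1.00 : MG
[bead] NA1 TN6q -0.25 : NA C1A C4A
[bead] NB1 TN6q -0.25 : NB C1B C4B
[bead] NC1 TN6q -0.25 : NC C1C C4C
[bead] ND1 TN6q -0.25 : ND C1D C4D
[bead] TAB1 TC5 0.00 : C3A CHA
[bead] TAB2 TC5 0.00 : CHA C2B
[bead] TBC1 TC5 0.00 : C3B CHB
[bead] TBC2 TC5 0.00 : CHB C2C
[bead] TCD1 TC5 0.00 : C3C CHC
[bead] TCD2 TC5 0.00 : CHC C2D
[bead] TDA1 TC5 0.00 : C3D CHD
[bead] TDA2 TC5 0.00 : CHD C2A
[bead] RE1 SC5 0.00 : CE1 CE2 CE3 OE1
[bead] SM1 TC5 0.00 : CM3 CM4
[bead] SV1 SC5 0.00 : CV1 CV2 CM1
[bead] SE1 SC5 0.00 : CT1 CT2 CM2
[bead] EST1 N4a 0.00 : CAA OAA OAB CAB
[bead] EST2 N4a 0.00 : CBA OBA OBB CBB
[bead] PHY1 C1 0.00 : PH1 PH2 PH3 PH4 PH5
[bead] PHY2 C1 0.00 : PH6 PH7 PH8 PH9 PH10
[bead] PHY3 C1 0.00 : PH11 PH12 PH13 PH14 PH15
[bead] PHY4 C1 0.00 : PH16 PH17 PH18 PH19 PH20
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
MGB NA1
MGB NB1
MGB NC1
MGB ND1
NA1 NB1
NB1 NC1
NC1 ND1
ND1 NA1
NA1 NC1
NB1 ND1
MGB TAB1
MGB TAB2
MGB TBC1
MGB TBC2
MGB TCD1
MGB TCD2
MGB TDA1
MGB TDA2
RE1 TCD1
RE1 NC1
SM1 TBC1
SM1 NB1
SV1 TDA2
SV1 NA1
SE1 TCD2
SE1 ND1
EST1 RE1
EST2 TDA1
EST2 PHY1
PHY1 PHY2
PHY2 PHY3
PHY3 PHY4
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
TCD1 RE1 EST1
NC1 RE1 EST1
TCD1 RE1 NC1
TBC1 SM1 NB1
TDA2 SV1 NA1
TCD2 SE1 ND1
TDA1 EST2 PHY1
EST2 PHY1 PHY2
PHY1 PHY2 PHY3
PHY2 PHY3 PHY4
[impropers]
NA1 TAB1 TAB2 NB1
NB1 TBC1 TBC2 NC1
NC1 TCD1 TCD2 ND1
ND1 TDA1 TDA2 NA1
MGB NA1 NB1 NC1
MGB NB1 NC1 ND1
MGB NC1 ND1 NA1
MGB ND1 NA1 NB1
TAB1 TAB2 TBC1 TBC2
TBC1 TBC2 TCD1 TCD2
TCD1 TCD2 TDA1 TDA2
TDA1 TDA2 TAB1 TAB2
TCD1 NC1 RE1 EST1
TBC1 NB1 SM1 MGB
TDA2 NA1 SV1 MGB
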
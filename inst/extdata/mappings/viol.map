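; violaxanthin (VIOL): 10 beads, 11 bonds, 8 angles
; united-atom table is a synthetic formula-accurate reconstruction;
; bead graph totals (beads/bonds/angles/impropers, charges) are authoritative.
[molecule] VIOL 0
[atoms]
C1 C 14.027 8
C2 C 14.027 8
C3 C 13.019 7
C4 C 13.019 7
C5 C 12.011 6
C6 C 12.011 6
C7 C 15.035 9
C8 C 15.035 9
C9 C 15.035 9
O1 O 17.007 9
O2 O 15.999 8
C10 C 13.019 7
C11 C 13.019 7
C12 C 15.035 9
C13 C 12.011 6
C14 C 13.019 7
C15 C 12.011 6
C16 C 13.019 7
C17 C 12.011 6
C18 C 15.035 9
C19 C 13.019 7
C20 C 13.019 7
C21 C 13.019 7
C22 C 12.011 6
C23 C 15.035 9
C24 C 13.019 7
C25 C 13.019 7
C26 C 12.011 6
C27 C 13.019 7
C28 C 13.019 7
C29 C 15.035 9
C30 C 13.019 7
C31 C 12.011 6
C32 C 14.027 8
C33 C 14.027 8
C34 C 13.019 7
C35 C 13.019 7
C36 C 12.011 6
C37 C 12.011 6
C38 C 15.035 9
C39 C 15.035 9
C40 C 15.035 9
O3 O 17.007 9
O4 O 15.999 8
[bead] P1A P1 0.00 : C1 C2 C3 O1
[bead] N1A N1a 0.00 : C4 C5 C6 O2
[bead] SCA SC2 0.00 : C7 C8 C9
[bead] L1 C2h 0.00 : C10 C11 C12 C13 C14 C15
[bead] L2 C2h 0.00 : C16 C17 C18 C19 C20
[bead] L3 C2h 0.00 : C21 C22 C23 C24 C25
[bead] L4 C2h 0.00 : C26 C27 C28 C29 C30 C31
[bead] P1B P1 0.00 : C32 C33 C34 O3
[bead] N1B N1a 0.00 : C35 C36 C37 O4
[bead] SCB SC2 0.00 : C38 C39 C40
[bonds]
P1A N1A
N1A SCA
SCA P1A
P1A L1
L1 L2
L2 L3
L3 L4
L4 P1B
P1B N1B
N1B SCB
SCB P1B
[angles]
N1A P1A L1
SCA P1A L1
P1A L1 L2
L1 L2 L3
L2 L3 L4
L3 L4 P1B
L4 P1B N1B
L4 P1B SCB
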
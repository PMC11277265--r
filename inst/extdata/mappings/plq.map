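; plastoquinone-9 (PLQ): 13 beads, 13 bonds, 12 angles
; united-atom table is a synthetic formula-accurate reconstruction;
; bead graph totals (beads/bonds/angles/impropers, charges) are authoritative.
[molecule] PLQ 0
[atoms]
C1 C 12.011 6
O1 O 15.999 8
C2 C 12.011 6
C3 C 12.011 6
C4 C 12.011 6
O2 O 15.999 8
C5 C 12.011 6
C6 C 13.019 7
C7 C 15.035 9
C8 C 15.035 9
C9 C 14.027 8
C10 C 12.011 6
C11 C 15.035 9
C12 C 13.019 7
C13 C 14.027 8
C14 C 14.027 8
C15 C 12.011 6
C16 C 15.035 9
C17 C 13.019 7
C18 C 14.027 8
C19 C 14.027 8
C20 C 12.011 6
C21 C 15.035 9
C22 C 13.019 7
C23 C 14.027 8
C24 C 14.027 8
C25 C 12.011 6
C26 C 15.035 9
C27 C 13.019 7
C28 C 14.027 8
C29 C 14.027 8
C30 C 12.011 6
C31 C 15.035 9
C32 C 13.019 7
C33 C 14.027 8
C34 C 14.027 8
C35 C 12.011 6
C36 C 15.035 9
C37 C 13.019 7
C38 C 14.027 8
C39 C 14.027 8
C40 C 12.011 6
C41 C 15.035 9
C42 C 13.019 7
C43 C 14.027 8
C44 C 14.027 8
C45 C 12.011 6
C46 C 15.035 9
C47 C 13.019 7
C48 C 14.027 8
C49 C 14.027 8
C50 C 12.011 6
C51 C 15.035 9
C52 C 13.019 7
C53 C 15.035 9
[bead] QA TN3a 0.00 : C1 O1
[bead] RB TC3 0.00 : C2 C3
[bead] QB TN3a 0.00 : C4 O2
[bead] CB C2 0.00 : C5 C6 C7 C8
[bead] T1 C2 0.00 : C9 C10 C11 C12 C13
[bead] T2 C2 0.00 : C14 C15 C16 C17 C18
[bead] T3 C2 0.00 : C19 C20 C21 C22 C23
[bead] T4 C2 0.00 : C24 C25 C26 C27 C28
[bead] T5 C2 0.00 : C29 C30 C31 C32 C33
[bead] T6 C2 0.00 : C34 C35 C36 C37 C38
[bead] T7 C2 0.00 : C39 C40 C41 C42 C43
[bead] T8 C2 0.00 : C44 C45 C46 C47 C48
[bead] T9 C2 0.00 : C49 C50 C51 C52 C53
[bonds]
QA RB
RB QB
QB CB
CB QA
CB T1
T1 T2
T2 T3
T3 T4
T4 T5
T5 T6
T6 T7
T7 T8
T8 T9
[angles]
QA RB QB
QA CB QB
RB QA CB
QB CB T1
CB T1 T2
T1 T2 T3
T2 T3 T4
T3 T4 T5
T4 T5 T6
T5 T6 T7
T6 T7 T8
T7 T8 T9
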
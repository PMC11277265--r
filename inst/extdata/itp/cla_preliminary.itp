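; CLA: preliminary parameters (idealized geometry)
[ moleculetype ]
; name nrexcl
CLA 1

[ atoms ]
; nr type resnr residue atom cgnr charge mass
    1   TQ3p     1    CLA    MGB     1     1.0000    36.00
    2   TN6q     1    CLA    NA1     2    -0.2500    36.00
    3   TN6q     1    CLA    NB1     3    -0.2500    36.00
    4   TN6q     1    CLA    NC1     4    -0.2500    36.00
    5   TN6q     1    CLA    ND1     5    -0.2500    36.00
    6    TC5     1    CLA   TAB1     6     0.0000    36.00
    7    TC5     1    CLA   TAB2     7     0.0000    36.00
    8    TC5     1    CLA   TBC1     8     0.0000    36.00
    9    TC5     1    CLA   TBC2     9     0.0000    36.00
   10    TC5     1    CLA   TCD1    10     0.0000    36.00
   11    TC5     1    CLA   TCD2    11     0.0000    36.00
   12    TC5     1    CLA   TDA1    12     0.0000    36.00
   13    TC5     1    CLA   TDA2    13     0.0000    36.00
   14    SC5     1    CLA    RE1    14     0.0000    54.00
   15    TC5     1    CLA    SM1    15     0.0000    36.00
   16    SC5     1    CLA    SV1    16     0.0000    54.00
   17    SC5     1    CLA    SE1    17     0.0000    54.00
   18    N4a     1    CLA   EST1    18     0.0000    72.00
   19    N4a     1    CLA   EST2    19     0.0000    72.00
   20     C1     1    CLA   PHY1    20     0.0000    72.00
   21     C1     1    CLA   PHY2    21     0.0000    72.00
   22     C1     1    CLA   PHY3    22     0.0000    72.00
   23     C1     1    CLA   PHY4    23     0.0000    72.00

[ bonds ]
    2     6     1     0.244942      5000.00
    6     7     1     0.247795      5000.00
    7     3     1     0.265671      5000.00
    3     8     1     0.242573      5000.00
    8     9     1     0.234164      5000.00
    9     4     1     0.264621      5000.00
    4    10     1     0.232054      5000.00
   10    11     1     0.245978      5000.00
   11     5     1     0.259257      5000.00
    5    12     1     0.230363      5000.00
   12    13     1     0.259405      5000.00
   13     2     1     0.214697      5000.00
    1     2     1     0.203956      5000.00
    1     3     1     0.196469      5000.00
    1     4     1     0.213838      5000.00
    1     5     1     0.227169      5000.00
    2     3     1     0.261349      5000.00
    3     4     1     0.211696      5000.00
    4     5     1     0.229962      5000.00
    5     2     1     0.215014      5000.00
    2     4     1     0.326301      5000.00
    3     5     1     0.323270      5000.00
    1     6     1     0.256619      5000.00
    1     7     1     0.248517      5000.00
    1     8     1     0.268931      5000.00
    1     9     1     0.252911      5000.00
    1    10     1     0.297884      5000.00
    1    11     1     0.244329      5000.00
    1    12     1     0.314413      5000.00
    1    13     1     0.311156      5000.00
   14    10     1     0.289104      5000.00
   14     4     1     0.273435      5000.00
   15     8     1     0.248666      5000.00
   15     3     1     0.250040      5000.00
   16    13     1     0.273360      5000.00
   16     2     1     0.294146      5000.00
   17    11     1     0.273758      5000.00
   17     5     1     0.288909      5000.00
   18    14     1     0.341639      5000.00
   19    12     1     0.322440      5000.00
   19    20     1     0.365232      5000.00
   20    21     1     0.369106      5000.00
   21    22     1     0.371267      5000.00
   22    23     1     0.370972      5000.00

[ angles ]
    2     6     7     2    76.047989       100.00
    6     7     3     2   100.485982       100.00
    7     3     8     2    66.001752       100.00
    3     8     9     2    93.900987       100.00
    8     9     4     2    77.374180       100.00
    9     4    10     2    61.769775       100.00
    4    10    11     2    97.252593       100.00
   10    11     5     2    57.987117       100.00
   11     5    12     2   145.698153       100.00
    5    12    13     2   104.103573       100.00
   12    13     2     2    56.825950       100.00
   13     2     6     2   108.463776       100.00
   10    14    18     2   121.429576       100.00
    4    14    18     2   159.632456       100.00
   10    14     4     2    48.627193       100.00
    8    15     3     2    58.208292       100.00
   13    16     2     2    44.270204       100.00
   11    17     5     2    54.792894       100.00
   12    19    20     2    72.790947       100.00
   19    20    21     2    66.843374       100.00
   20    21    22     2    46.925197       100.00
   21    22    23     2   139.408926       100.00

[ dihedrals ]
    2     6     7     3     2    24.893926        50.00
    3     8     9     4     2   -19.775743        50.00
    4    10    11     5     2   -48.219254        50.00
    5    12    13     2     2    20.513784        50.00
    1     2     3     4     2   -57.414355        50.00
    1     3     4     5     2   -50.653158        50.00
    1     4     5     2     2   -41.501688        50.00
    1     5     2     3     2   -45.838340        50.00
    6     7     8     9     2     2.831611        50.00
    8     9    10    11     2    89.770587        50.00
   10    11    12    13     2   136.083517        50.00
   12    13     6     7     2  -125.343306        50.00
   10     4    14    18     2   -67.918834        50.00
    8     3    15     1     2   -33.702770        50.00
   13     2    16     1     2   -41.735617        50.00
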
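
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts
           A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  Y  V   A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 M   -1 -2 -2 -4 -2  0 -2 -3 -2  1  2 -2  6  0 -3 -2 -1 -2 -1  1    0   0   0   0   0   0   0   0   0   0   0   0 100   0   0   0   0   0   0   0  0.33 0.00
    2 K   -1  2  0 -1 -3  1  1 -2 -1 -3 -3  5 -2 -4 -1  0 -1 -3 -2 -3    0   0   0   0   0   0   0   0   0   0   0 100   0   0   0   0   0   0   0   0  0.51 0.00
    3 T    0 -1  0 -1 -1 -1 -1 -2 -2 -1 -1 -1 -1 -2 -1  2  5 -3 -2  0    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0 100   0   0   0  0.46 0.00
    4 A    4 -2 -2 -2  0 -1 -1  0 -2 -2 -2 -1 -1 -3 -1  1  0 -3 -2  0  100   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.40 0.00
    5 Y   -2 -2 -2 -4 -3 -2 -2 -3  2 -2 -1 -2 -1  3 -3 -2 -2  2  8 -1    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0 100   0  0.85 0.00
    6 I   -2 -3 -4 -4 -1 -3 -3 -4 -3  3  3 -3  2  0 -3 -3 -1 -2 -1  2    0   0   0   0   0   0   0   0   0  50  50   0   0   0   0   0   0   0   0   0  0.36 0.00
    7 A    4 -2 -2 -2  0 -1 -1  0 -2 -2 -2 -1 -1 -3 -1  1  0 -3 -2  0  100   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.40 0.00
    8 K   -1  2  0 -1 -3  1  1 -2 -1 -3 -3  5 -2 -4 -1  0 -1 -3 -2 -3    0   0   0   0   0   0   0   0   0   0   0 100   0   0   0   0   0   0   0   0  0.51 0.00
    9 Q   -1  1  0  0 -3  6  2 -2  1 -3 -2  1  0 -4 -1  0 -1 -2 -2 -3    0   0   0   0   0 100   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.64 0.00
   10 R   -2  6 -1 -2 -4  1  0 -3  0 -3 -2  2 -2 -3 -2 -1 -1 -3 -2 -3    0 100   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.74 0.00
   11 Q   -1  1  0  0 -3  6  2 -2  1 -3 -2  1  0 -4 -1  0 -1 -2 -2 -3    0   0   0   0   0 100   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.64 0.00
   12 I   -2 -3 -4 -4 -1 -3 -4 -4 -4  5  2 -3  1  0 -3 -3 -1 -3 -2  3    0   0   0   0   0   0   0   0   0 100   0   0   0   0   0   0   0   0   0   0  0.38 0.00
   13 S    1 -1  1  0 -1  0  0  0 -1 -3 -3  0 -2 -3 -1  4  2 -3 -2 -2    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0 100   0   0   0   0  0.45 0.00
   14 F   -3 -3 -3 -4 -3 -4 -4 -4 -1  0  0 -4  0  7 -4 -3 -2  1  3 -1    0   0   0   0   0   0   0   0   0   0   0   0   0 100   0   0   0   0   0   0  0.73 0.00
   15 V    0 -3 -3 -4 -1 -3 -3 -4 -4  3  1 -3  1 -1 -3 -2  0 -3 -1  4    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0 100  0.34 0.00

                      K         Lambda
Standard Ungapped    0.1306     0.3309
Standard Gapped      0.0410     0.2670
PSI Ungapped         0.1306     0.3309
PSI Gapped           0.0410     0.2670
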
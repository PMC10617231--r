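
Synthetic position-specific scoring matrix in the PSI-BLAST -out_ascii_pssm dialect (hand-written test fixture, not a real NR search)
            A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 G    -1  -3  -2  -2  -3  -3  -3   6  -3  -5  -5  -2  -4  -4  -3  -1  -2  -3  -4  -4    0   0   0   0   0   0   0 100   0   0   0   0   0   0   0   0   0   0   0   0  1.20 0.30
    2 V     0  -3  -3  -4  -1  -2  -3  -4  -4   3   1  -3   1  -1  -3  -2   0  -3  -1   4    0   0   0   0   0   0   0   0   0  20   0   0   0   0   0   0   0   0   0  80  0.80 0.30
    3 A     5  -2  -2  -2  -1  -1  -1   0  -2  -2  -2  -1  -1  -3  -1   1   0  -3  -2   0   90   0   0   0   0   0   0   0   0   0   0   0   0   0   0  10   0   0   0   0  0.95 0.30
    4 K    -1   2   0  -1  -4   1   1  -2  -1  -3  -3   5  -2  -4  -1   0  -1  -3  -2  -3    0  10   0   0   0   0   0   0   0   0   0  90   0   0   0   0   0   0   0   0  1.05 0.30
    5 F    -3  -3  -4  -4  -3  -4  -4  -4  -2   0   0  -4   0   7  -4  -3  -2   1   3  -1    0   0   0   0   0   0   0   0   0   0   0   0   0 100   0   0   0   0   0   0  1.10 0.30

                      K         Lambda
Standard Ungapped    0.1347     0.3195
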
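14
glycerol C3H8O3 reference conformer (Angstrom)
C  1.230234 0.671187 -0.386866
C  0.133385 0.174978 0.552053
C  -0.935106 -0.637542 -0.183769
O  1.878799 -0.414620 -1.037557
O  -0.494280 1.296079 1.187529
O  -1.969927 -0.971174 0.749656
H  2.616485 -0.034382 -1.546396
H  1.975484 1.241981 0.178213
H  0.815575 1.342597 -1.147080
H  0.568080 -0.445419 1.344506
H  -1.296833 0.918423 1.602818
H  -0.523491 -1.561979 -0.599501
H  -1.395116 -0.046979 -0.982600
H  -2.603289 -1.533150 0.268996
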
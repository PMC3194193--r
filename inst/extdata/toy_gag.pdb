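ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C
ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C
ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00  0.00           O
ATOM      5  N   ALA A   2       3.332   1.536   0.000  1.00  0.00           N
ATOM      6  CA  ALA A   2       3.988   2.839   0.000  1.00  0.00           C
ATOM      7  CB  ALA A   2       5.501   2.706   0.000  1.00  0.00           C
ATOM      8  C   ALA A   2       3.534   3.668   1.203  1.00  0.00           C
ATOM      9  O   ALA A   2       3.165   3.115   2.239  1.00  0.00           O
ATOM     10  N   GLY A   3       3.557   4.992   1.066  1.00  0.00           N
ATOM     11  CA  GLY A   3       3.142   5.898   2.133  1.00  0.00           C
ATOM     12  C   GLY A   3       1.644   6.150   2.095  1.00  0.00           C
ATOM     13  O   GLY A   3       1.003   6.029   1.049  1.00  0.00           O
END
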
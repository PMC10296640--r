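HEADER    HAND-WRITTEN TEST PEPTIDE
REMARK    synthetic miniature: 3-residue chain A, 1-residue chain B, water
ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N
ATOM      2  CA  ALA A   1       1.460   0.000   0.000  1.00 11.20           C
ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  9.80           C
ATOM      4  O   ALA A   1       1.400   2.400   0.000  1.00 12.00           O
ATOM      5  CB  ALA A   1       2.000  -0.800   1.200  1.00 13.10           C
ATOM      6  HB1 ALA A   1       2.500  -1.500   1.700  1.00 13.10           H
ATOM      7  N   GLY A   2       3.300   1.500   0.000  1.00 14.00           N
ATOM      8  CA  GLY A   2       4.000   2.700   0.000  1.00 15.30           C
ATOM      9  C   GLY A   2       5.500   2.600   0.000  1.00 13.90           C
ATOM     10  O   GLY A   2       6.100   1.500   0.000  1.00 16.00           O
ATOM     11  N   SER A   3       6.100   3.700   0.000  1.00 15.00           N
ATOM     12  CA  SER A   3       7.500   3.800   0.200  1.00 16.10           C
ATOM     13  C   SER A   3       8.200   5.000   0.600  1.00 14.70           C
ATOM     14  O   SER A   3       7.600   6.100   0.600  1.00 17.40           O
ATOM     15  CB  SER A   3       8.000   2.900   1.300  1.00 18.00           C
ATOM     16  OG ASER A   3       8.400   1.700   0.900  0.60 19.00           O
ATOM     17  OG BSER A   3       9.400   3.200   1.600  0.40 19.50           O
TER
ATOM     18  N   ALA B   1      10.000   0.000   0.000  1.00 20.00           N
ATOM     19  CA  ALA B   1      11.500   0.000   0.000  1.00 21.00           C
ATOM     20  C   ALA B   1      12.200   1.300   0.000  1.00 19.60           C
ATOM     21  O   ALA B   1      11.600   2.400   0.000  1.00 22.00           O
ATOM     22  CB  ALA B   1      12.000  -1.000   1.200  1.00 23.00           C
TER
HETATM   23  O   HOH A 101     20.000  20.000  20.000  1.00 30.00           O
END
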
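REMARK   SYNTHETIC SxIP peptide fixture (idealized coordinates, chain P)
ATOM      1  N   SER P5477       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  SER P5477       1.460   0.000   0.000  1.00  0.00           C
ATOM      3  C   SER P5477       2.000   1.420   0.000  1.00  0.00           C
ATOM      4  O   SER P5477       1.300   2.430   0.100  1.00  0.00           O
ATOM      5  CB  SER P5477       2.000  -0.800   1.200  1.00  0.00           C
ATOM      6  OG  SER P5477       1.600  -2.150   1.200  1.00  0.00           O
ATOM      7  N   LYS P5478       3.330   1.500   0.000  1.00  0.00           N
ATOM      8  CA  LYS P5478       4.000   2.800   0.000  1.00  0.00           C
ATOM      9  C   LYS P5478       5.500   2.700   0.100  1.00  0.00           C
ATOM     10  O   LYS P5478       6.100   1.640   0.200  1.00  0.00           O
ATOM     11  CB  LYS P5478       3.600   3.600  -1.250  1.00  0.00           C
ATOM     12  N   ILE P5479       6.150   3.860   0.000  1.00  0.00           N
ATOM     13  CA  ILE P5479       7.600   3.900   0.100  1.00  0.00           C
ATOM     14  C   ILE P5479       8.200   5.300   0.000  1.00  0.00           C
ATOM     15  O   ILE P5479       7.500   6.320  -0.100  1.00  0.00           O
ATOM     16  CB  ILE P5479       8.200   3.100   1.300  1.00  0.00           C
ATOM     17  CG1 ILE P5479       9.700   3.000   1.200  1.00  0.00           C
ATOM     18  CG2 ILE P5479       7.600   1.700   1.400  1.00  0.00           C
ATOM     19  CD1 ILE P5479      10.300   2.200   2.350  1.00  0.00           C
ATOM     20  N   PRO P5480       9.530   5.400   0.050  1.00  0.00           N
ATOM     21  CA  PRO P5480      10.200   6.700   0.000  1.00  0.00           C
ATOM     22  C   PRO P5480      11.700   6.550   0.150  1.00  0.00           C
ATOM     23  O   PRO P5480      12.300   5.500   0.300  1.00  0.00           O
ATOM     24  CB  PRO P5480       9.800   7.500   1.250  1.00  0.00           C
ATOM     25  CG  PRO P5480       9.300   6.500   2.300  1.00  0.00           C
ATOM     26  CD  PRO P5480       9.900   5.200   1.900  1.00  0.00           C
TER
END
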
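HEADER    SYNTHETIC TEST STRUCTURE                01-JAN-26   XXXX
TITLE     SYNTHETIC MINI HELIX FIXTURE FOR B-FACTOR MAPPING TESTS
REMARK   3  THIS IS A SYNTHETIC FIXTURE, NOT A DEPOSITED STRUCTURE
ATOM      1  N   MET A  91      -0.399   2.265   0.380  1.00 20.00           N
ATOM      2  CA  MET A  91      -2.161  -0.787   0.760  1.00 20.00           C
ATOM      3  C   MET A  91       1.150  -1.992   1.140  1.00 20.00           C
ATOM      4  O   MET A  91       1.762   1.478   1.520  1.00 20.00           O
ATOM      5  N   LEU A  92      -1.762   1.478   1.900  1.00 20.00           N
ATOM      6  CA  LEU A  92      -1.150  -1.992   2.280  1.00 20.00           C
ATOM      7  C   LEU A  92       2.161  -0.787   2.660  1.00 20.00           C
ATOM      8  O   LEU A  92       0.399   2.265   3.040  1.00 20.00           O
ATOM      9  N   THR A  93      -2.300   0.000   3.420  1.00 20.00           N
ATOM     10  CA  THR A  93       0.399  -2.265   3.800  1.00 20.00           C
ATOM     11  C   THR A  93       2.161   0.787   4.180  1.00 20.00           C
ATOM     12  O   THR A  93      -1.150   1.992   4.560  1.00 20.00           O
ATOM     13  N   ASN A  94      -1.762  -1.478   4.940  1.00 20.00           N
ATOM     14  CA  ASN A  94       1.762  -1.478   5.320  1.00 20.00           C
ATOM     15  C   ASN A  94       1.150   1.992   5.700  1.00 20.00           C
ATOM     16  O   ASN A  94      -2.161   0.787   6.080  1.00 20.00           O
ATOM     17  N   ALA A  95      -0.399  -2.265   6.460  1.00 20.00           N
ATOM     18  CA  ALA A  95       2.300  -0.000   6.840  1.00 20.00           C
ATOM     19  C   ALA A  95      -0.399   2.265   7.220  1.00 20.00           C
ATOM     20  O   ALA A  95      -2.161  -0.787   7.600  1.00 20.00           O
ATOM     21  N   ARG A  96       1.150  -1.992   7.980  1.00 20.00           N
ATOM     22  CA  ARG A  96       1.762   1.478   8.360  1.00 20.00           C
ATOM     23  C   ARG A  96      -1.762   1.478   8.740  1.00 20.00           C
ATOM     24  O   ARG A  96      -1.150  -1.992   9.120  1.00 20.00           O
ATOM     25  N   ASP A  97       2.161  -0.787   9.500  1.00 20.00           N
ATOM     26  CA  ASP A  97       0.399   2.265   9.880  1.00 20.00           C
ATOM     27  C   ASP A  97      -2.300  -0.000  10.260  1.00 20.00           C
ATOM     28  O   ASP A  97       0.399  -2.265  10.640  1.00 20.00           O
ATOM     29  N   ILE A  98       2.161   0.787  11.020  1.00 20.00           N
ATOM     30  CA  ILE A  98      -1.150   1.992  11.400  1.00 20.00           C
ATOM     31  C   ILE A  98      -1.762  -1.478  11.780  1.00 20.00           C
ATOM     32  O   ILE A  98       1.762  -1.478  12.160  1.00 20.00           O
ATOM     33  N   VAL A  99       1.150   1.992  12.540  1.00 20.00           N
ATOM     34  CA  VAL A  99      -2.161   0.787  12.920  1.00 20.00           C
ATOM     35  C   VAL A  99      -0.399  -2.265  13.300  1.00 20.00           C
ATOM     36  O   VAL A  99       2.300  -0.000  13.680  1.00 20.00           O
ATOM     37  N   GLY A 100      -0.399   2.265  14.060  1.00 20.00           N
ATOM     38  CA  GLY A 100      -2.161  -0.787  14.440  1.00 20.00           C
ATOM     39  C   GLY A 100       1.150  -1.992  14.820  1.00 20.00           C
ATOM     40  O   GLY A 100       1.762   1.478  15.200  1.00 20.00           O
ATOM     41  N   THR A 101      -1.762   1.478  15.580  1.00 20.00           N
ATOM     42  CA  THR A 101      -1.150  -1.992  15.960  1.00 20.00           C
ATOM     43  C   THR A 101       2.161  -0.787  16.340  1.00 20.00           C
ATOM     44  O   THR A 101       0.399   2.265  16.720  1.00 20.00           O
ATOM     45  N   LEU A 102      -2.300  -0.000  17.100  1.00 20.00           N
ATOM     46  CA  LEU A 102       0.399  -2.265  17.480  1.00 20.00           C
ATOM     47  C   LEU A 102       2.161   0.787  17.860  1.00 20.00           C
ATOM     48  O   LEU A 102      -1.150   1.992  18.240  1.00 20.00           O
TER      49      LEU A 102
MASTER        0    0    0    0    0    0    0    0   48    1    0    0
END
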
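C
CC
CCC
CCCC
CC(C)(C)C
CCO
CCCO
CC(O)C
CCOCC
CC=O
CCC=O
CC(=O)C
CCC(=O)C
CC(=O)O
COC(=O)C
CCOC(=O)C
CCC(=O)OC
CCN
CCCN
CC(N)C
CC#N
CC(=O)N
CNC(=O)C
CCS
CSCC
CC=C
CC=CC
C#C
CC#C
c1ccccc1
Cc1ccccc1
CCc1ccccc1
c1cccnc1
Cc1ccncc1
c1ccc2c(c1)cccc2
c1ccco1
c1cccs1
Oc1ccccc1
COc1ccccc1
Nc1ccccc1
CC(=O)c1ccccc1
COC(=O)c1ccccc1
C1CCCCC1
C1CCCC1
C1CCCO1
CC1CCCCC1
FC(F)F
BrCCBr
CCCl
CCBr
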
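residue,plb
ALA,0.9
ARG,1
ASN,0.8
ASP,0.7
CYS,1.2
GLN,0.8
GLU,0.7
GLY,0.9
HIS,1.4
ILE,1.3
LEU,1.3
LYS,0.8
MET,1.5
PHE,1.7
PRO,0.8
SER,0.8
THR,0.9
TRP,2
TYR,1.6
VAL,1.1
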
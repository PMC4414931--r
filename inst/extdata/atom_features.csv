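residue,atom,ptype,propensity
ALA,N,donor,0.5
ALA,CA,none,0.5
ALA,C,none,0.5
ALA,O,acceptor,0.5
ALA,OXT,acceptor,0.5
ALA,CB,hydrophobic,0.9
ARG,N,donor,0.5
ARG,CA,none,0.5
ARG,C,none,0.5
ARG,O,acceptor,0.5
ARG,OXT,acceptor,0.5
ARG,CB,hydrophobic,1
ARG,CG,hydrophobic,1
ARG,CD,hydrophobic,1
ARG,NE,donor,1
ARG,CZ,positive,1
ARG,NH1,positive,1
ARG,NH2,positive,1
ASN,N,donor,0.5
ASN,CA,none,0.5
ASN,C,none,0.5
ASN,O,acceptor,0.5
ASN,OXT,acceptor,0.5
ASN,CB,hydrophobic,0.8
ASN,CG,none,0.8
ASN,OD1,acceptor,0.8
ASN,ND2,donor,0.8
ASP,N,donor,0.5
ASP,CA,none,0.5
ASP,C,none,0.5
ASP,O,acceptor,0.5
ASP,OXT,acceptor,0.5
ASP,CB,hydrophobic,0.7
ASP,CG,none,0.7
ASP,OD1,negative,0.7
ASP,OD2,negative,0.7
CYS,N,donor,0.5
CYS,CA,none,0.5
CYS,C,none,0.5
CYS,O,acceptor,0.5
CYS,OXT,acceptor,0.5
CYS,CB,hydrophobic,1.2
CYS,SG,donor,1.2
GLN,N,donor,0.5
GLN,CA,none,0.5
GLN,C,none,0.5
GLN,O,acceptor,0.5
GLN,OXT,acceptor,0.5
GLN,CB,hydrophobic,0.8
GLN,CG,hydrophobic,0.8
GLN,CD,none,0.8
GLN,OE1,acceptor,0.8
GLN,NE2,donor,0.8
GLU,N,donor,0.5
GLU,CA,none,0.5
GLU,C,none,0.5
GLU,O,acceptor,0.5
GLU,OXT,acceptor,0.5
GLU,CB,hydrophobic,0.7
GLU,CG,hydrophobic,0.7
GLU,CD,none,0.7
GLU,OE1,negative,0.7
GLU,OE2,negative,0.7
GLY,N,donor,0.5
GLY,CA,none,0.5
GLY,C,none,0.5
GLY,O,acceptor,0.5
GLY,OXT,acceptor,0.5
HIS,N,donor,0.5
HIS,CA,none,0.5
HIS,C,none,0.5
HIS,O,acceptor,0.5
HIS,OXT,acceptor,0.5
HIS,CB,hydrophobic,1.4
HIS,CG,aromatic,1.4
HIS,ND1,donor_acceptor,1.4
HIS,CD2,aromatic,1.4
HIS,CE1,aromatic,1.4
HIS,NE2,donor_acceptor,1.4
ILE,N,donor,0.5
ILE,CA,none,0.5
ILE,C,none,0.5
ILE,O,acceptor,0.5
ILE,OXT,acceptor,0.5
ILE,CB,hydrophobic,1.3
ILE,CG1,hydrophobic,1.3
ILE,CG2,hydrophobic,1.3
ILE,CD1,hydrophobic,1.3
LEU,N,donor,0.5
LEU,CA,none,0.5
LEU,C,none,0.5
LEU,O,acceptor,0.5
LEU,OXT,acceptor,0.5
LEU,CB,hydrophobic,1.3
LEU,CG,hydrophobic,1.3
LEU,CD1,hydrophobic,1.3
LEU,CD2,hydrophobic,1.3
LYS,N,donor,0.5
LYS,CA,none,0.5
LYS,C,none,0.5
LYS,O,acceptor,0.5
LYS,OXT,acceptor,0.5
LYS,CB,hydrophobic,0.8
LYS,CG,hydrophobic,0.8
LYS,CD,hydrophobic,0.8
LYS,CE,hydrophobic,0.8
LYS,NZ,positive,0.8
MET,N,donor,0.5
MET,CA,none,0.5
MET,C,none,0.5
MET,O,acceptor,0.5
MET,OXT,acceptor,0.5
MET,CB,hydrophobic,1.5
MET,CG,hydrophobic,1.5
MET,SD,hydrophobic,1.5
MET,CE,hydrophobic,1.5
PHE,N,donor,0.5
PHE,CA,none,0.5
PHE,C,none,0.5
PHE,O,acceptor,0.5
PHE,OXT,acceptor,0.5
PHE,CB,hydrophobic,1.7
PHE,CG,aromatic,1.7
PHE,CD1,aromatic,1.7
PHE,CD2,aromatic,1.7
PHE,CE1,aromatic,1.7
PHE,CE2,aromatic,1.7
PHE,CZ,aromatic,1.7
PRO,N,none,0.5
PRO,CA,none,0.5
PRO,C,none,0.5
PRO,O,acceptor,0.5
PRO,OXT,acceptor,0.5
PRO,CB,hydrophobic,0.8
PRO,CG,hydrophobic,0.8
PRO,CD,hydrophobic,0.8
SER,N,donor,0.5
SER,CA,none,0.5
SER,C,none,0.5
SER,O,acceptor,0.5
SER,OXT,acceptor,0.5
SER,CB,hydrophobic,0.8
SER,OG,donor_acceptor,0.8
THR,N,donor,0.5
THR,CA,none,0.5
THR,C,none,0.5
THR,O,acceptor,0.5
THR,OXT,acceptor,0.5
THR,CB,hydrophobic,0.9
THR,OG1,donor_acceptor,0.9
THR,CG2,hydrophobic,0.9
TRP,N,donor,0.5
TRP,CA,none,0.5
TRP,C,none,0.5
TRP,O,acceptor,0.5
TRP,OXT,acceptor,0.5
TRP,CB,hydrophobic,2
TRP,CG,aromatic,2
TRP,CD1,aromatic,2
TRP,CD2,aromatic,2
TRP,NE1,donor,2
TRP,CE2,aromatic,2
TRP,CE3,aromatic,2
TRP,CZ2,aromatic,2
TRP,CZ3,aromatic,2
TRP,CH2,aromatic,2
TYR,N,donor,0.5
TYR,CA,none,0.5
TYR,C,none,0.5
TYR,O,acceptor,0.5
TYR,OXT,acceptor,0.5
TYR,CB,hydrophobic,1.6
TYR,CG,aromatic,1.6
TYR,CD1,aromatic,1.6
TYR,CD2,aromatic,1.6
TYR,CE1,aromatic,1.6
TYR,CE2,aromatic,1.6
TYR,CZ,aromatic,1.6
TYR,OH,donor_acceptor,1.6
VAL,N,donor,0.5
VAL,CA,none,0.5
VAL,C,none,0.5
VAL,O,acceptor,0.5
VAL,OXT,acceptor,0.5
VAL,CB,hydrophobic,1.1
VAL,CG1,hydrophobic,1.1
VAL,CG2,hydrophobic,1.1
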
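residue,atom_name,category
*,N,D
*,O,Ac
*,C,H
*,CA,H
*,OXT,N
ALA,CB,H
ARG,CB,H
ARG,CG,H
ARG,CD,H
ARG,NE,P
ARG,CZ,H
ARG,NH1,P
ARG,NH2,P
ASN,CB,H
ASN,CG,H
ASN,OD1,Ac
ASN,ND2,D
ASP,CB,H
ASP,CG,H
ASP,OD1,N
ASP,OD2,N
CYS,CB,H
CYS,SG,D
GLN,CB,H
GLN,CG,H
GLN,CD,H
GLN,OE1,Ac
GLN,NE2,D
GLU,CB,H
GLU,CG,H
GLU,CD,H
GLU,OE1,N
GLU,OE2,N
GLY,CA,H
HIS,CB,H
HIS,CG,Ar
HIS,ND1,P
HIS,CD2,Ar
HIS,CE1,Ar
HIS,NE2,P
ILE,CB,H
ILE,CG1,H
ILE,CG2,H
ILE,CD1,H
LEU,CB,H
LEU,CG,H
LEU,CD1,H
LEU,CD2,H
LYS,CB,H
LYS,CG,H
LYS,CD,H
LYS,CE,H
LYS,NZ,P
MET,CB,H
MET,CG,H
MET,SD,H
MET,CE,H
PHE,CB,H
PHE,CG,Ar
PHE,CD1,Ar
PHE,CD2,Ar
PHE,CE1,Ar
PHE,CE2,Ar
PHE,CZ,Ar
PRO,N,Ac
PRO,CB,H
PRO,CG,H
PRO,CD,H
SER,CB,H
SER,OG,D
THR,CB,H
THR,OG1,D
THR,CG2,H
TRP,CB,H
TRP,CG,Ar
TRP,CD1,Ar
TRP,CD2,Ar
TRP,NE1,D
TRP,CE2,Ar
TRP,CE3,Ar
TRP,CZ2,Ar
TRP,CZ3,Ar
TRP,CH2,Ar
TYR,CB,H
TYR,CG,Ar
TYR,CD1,Ar
TYR,CD2,Ar
TYR,CE1,Ar
TYR,CE2,Ar
TYR,CZ,Ar
TYR,OH,D
VAL,CB,H
VAL,CG1,H
VAL,CG2,H
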
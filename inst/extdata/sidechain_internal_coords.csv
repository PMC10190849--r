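# Idealized side-chain internal coordinates (heavy atoms only).
# Each atom is placed by torsion geometry from three previously placed atoms of
# the same residue: bond length to `parent` (Angstrom), bond angle
# gp-parent-atom (degrees), dihedral ggp-gp-parent-atom (degrees).
# Bond lengths/angles follow the Engh & Huber idealized parameter set rounded
# to typical values; default rotamers are extended (chi = 180) with branches
# at +/-60, aromatic rings planar.
# CB is placed by the builder for every non-glycine residue; rows below start
# at the gamma position.
resid,atom,parent,gp,ggp,bond,angle,torsion
ARG,CG,CB,CA,N,1.52,114.0,180
ARG,CD,CG,CB,CA,1.52,111.3,180
ARG,NE,CD,CG,CB,1.46,112.0,180
ARG,CZ,NE,CD,CG,1.33,124.2,180
ARG,NH1,CZ,NE,CD,1.33,120.0,0
ARG,NH2,CZ,NE,CD,1.33,120.0,180
ASN,CG,CB,CA,N,1.52,112.6,180
ASN,OD1,CG,CB,CA,1.23,120.8,0
ASN,ND2,CG,CB,CA,1.33,116.4,180
ASP,CG,CB,CA,N,1.52,112.6,180
ASP,OD1,CG,CB,CA,1.25,118.4,0
ASP,OD2,CG,CB,CA,1.25,118.4,180
CYS,SG,CB,CA,N,1.81,113.8,180
GLN,CG,CB,CA,N,1.52,114.0,180
GLN,CD,CG,CB,CA,1.52,112.6,180
GLN,OE1,CD,CG,CB,1.23,120.8,0
GLN,NE2,CD,CG,CB,1.33,116.4,180
GLU,CG,CB,CA,N,1.52,114.0,180
GLU,CD,CG,CB,CA,1.52,112.6,180
GLU,OE1,CD,CG,CB,1.25,118.4,0
GLU,OE2,CD,CG,CB,1.25,118.4,180
HIS,CG,CB,CA,N,1.50,113.8,180
HIS,ND1,CG,CB,CA,1.38,122.7,90
HIS,CD2,CG,CB,CA,1.36,131.0,-90
HIS,CE1,ND1,CG,CB,1.32,109.0,180
HIS,NE2,CD2,CG,CB,1.37,107.0,180
ILE,CG1,CB,CA,N,1.53,110.5,180
ILE,CG2,CB,CA,N,1.53,110.5,-60
ILE,CD1,CG1,CB,CA,1.52,113.0,180
LEU,CG,CB,CA,N,1.52,114.0,180
LEU,CD1,CG,CB,CA,1.52,110.5,180
LEU,CD2,CG,CB,CA,1.52,110.5,60
LYS,CG,CB,CA,N,1.52,114.0,180
LYS,CD,CG,CB,CA,1.52,111.3,180
LYS,CE,CD,CG,CB,1.52,111.3,180
LYS,NZ,CE,CD,CG,1.49,112.0,180
MET,CG,CB,CA,N,1.52,114.0,180
MET,SD,CG,CB,CA,1.80,112.7,180
MET,CE,SD,CG,CB,1.79,100.8,180
PHE,CG,CB,CA,N,1.50,113.8,180
PHE,CD1,CG,CB,CA,1.39,120.8,90
PHE,CD2,CG,CB,CA,1.39,120.8,-90
PHE,CE1,CD1,CG,CB,1.39,120.0,180
PHE,CE2,CD2,CG,CB,1.39,120.0,180
PHE,CZ,CE1,CD1,CG,1.39,120.0,0
PRO,CG,CB,CA,N,1.50,104.0,30
PRO,CD,CG,CB,CA,1.51,105.0,-35
SER,OG,CB,CA,N,1.42,110.8,180
THR,OG1,CB,CA,N,1.43,109.6,60
THR,CG2,CB,CA,N,1.52,110.5,180
TRP,CG,CB,CA,N,1.50,113.8,180
TRP,CD1,CG,CB,CA,1.37,127.0,90
TRP,CD2,CG,CB,CA,1.43,126.6,-90
TRP,NE1,CD1,CG,CB,1.38,110.0,180
TRP,CE2,CD2,CG,CB,1.41,107.0,180
TRP,CE3,CD2,CG,CB,1.40,133.9,0
TRP,CZ2,CE2,CD2,CG,1.40,122.0,180
TRP,CZ3,CE3,CD2,CG,1.39,118.8,180
TRP,CH2,CZ2,CE2,CD2,1.37,117.5,0
TYR,CG,CB,CA,N,1.50,113.8,180
TYR,CD1,CG,CB,CA,1.39,120.8,90
TYR,CD2,CG,CB,CA,1.39,120.8,-90
TYR,CE1,CD1,CG,CB,1.39,120.0,180
TYR,CE2,CD2,CG,CB,1.39,120.0,180
TYR,CZ,CE1,CD1,CG,1.39,120.0,0
TYR,OH,CZ,CE1,CD1,1.38,120.0,180
VAL,CG1,CB,CA,N,1.52,110.5,180
VAL,CG2,CB,CA,N,1.52,110.5,-60
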
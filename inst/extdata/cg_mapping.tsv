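# Default coarse-grain bead mapping.
# One row per bead; beads are built at the unweighted center of mass of
# source_atoms. Pyrimidines map to 6 beads, purines to 7, amino acids to
# 3-4. Guanine beads GB1-GB4 align one-to-one with adenine beads AB1-AB4
# (the O6/N2 substituents are merged into the shared-scaffold beads), so
# purine canonicalization is a pure re-typing.
residue_name	bead_name	role	type_code	charge	source_atoms
U	GP	phosphate	1	-1	P,OP1,OP2,O5'
U	GS1	sugar	2	0	C5',C4'
U	GS2	sugar	3	0	C3',C2',C1'
C	GP	phosphate	1	-1	P,OP1,OP2,O5'
C	GS1	sugar	2	0	C5',C4'
C	GS2	sugar	3	0	C3',C2',C1'
A	GP	phosphate	1	-1	P,OP1,OP2,O5'
A	GS1	sugar	2	0	C5',C4'
A	GS2	sugar	3	0	C3',C2',C1'
G	GP	phosphate	1	-1	P,OP1,OP2,O5'
G	GS1	sugar	2	0	C5',C4'
G	GS2	sugar	3	0	C3',C2',C1'
U	UB1	base	4	0	N1,C2,O2
U	UB2	base	5	0	N3,C4,O4
U	UB3	base	6	0	C5,C6
C	CB1	base	7	0	N1,C2,O2
C	CB2	base	8	0	N3,C4,N4
C	CB3	base	9	0	C5,C6
A	AB1	base	10	0	N9,C8
A	AB2	base	11	0	N7,C5
A	AB3	base	12	0	C6,N6
A	AB4	base	13	0	N1,C2,N3,C4
G	GB1	base	14	0	N9,C8
G	GB2	base	15	0	N7,C5
G	GB3	base	16	0	C6,O6
G	GB4	base	17	0	N1,C2,N3,C4,N2
GLY	MC1	mainchain	30	0	N,CA
GLY	MC2	mainchain	31	0	C,O
GLY	MC3	mainchain	32	0	CA,C
ALA	MC1	mainchain	30	0	N,CA
ALA	MC2	mainchain	31	0	C,O
ALA	SC1	sidechain	40	0	CB
SER	MC1	mainchain	30	0	N,CA
SER	MC2	mainchain	31	0	C,O
SER	SC1	sidechain	41	0	CB,OG
CYS	MC1	mainchain	30	0	N,CA
CYS	MC2	mainchain	31	0	C,O
CYS	SC1	sidechain	42	0	CB,SG
THR	MC1	mainchain	30	0	N,CA
THR	MC2	mainchain	31	0	C,O
THR	SC1	sidechain	43	0	CB,OG1,CG2
VAL	MC1	mainchain	30	0	N,CA
VAL	MC2	mainchain	31	0	C,O
VAL	SC1	sidechain	44	0	CB,CG1,CG2
LEU	MC1	mainchain	30	0	N,CA
LEU	MC2	mainchain	31	0	C,O
LEU	SC1	sidechain	45	0	CB,CG
LEU	SC2	sidechain	46	0	CD1,CD2
ILE	MC1	mainchain	30	0	N,CA
ILE	MC2	mainchain	31	0	C,O
ILE	SC1	sidechain	47	0	CB,CG1,CG2
ILE	SC2	sidechain	48	0	CD1
PRO	MC1	mainchain	30	0	N,CA
PRO	MC2	mainchain	31	0	C,O
PRO	SC1	sidechain	49	0	CB,CG,CD
MET	MC1	mainchain	30	0	N,CA
MET	MC2	mainchain	31	0	C,O
MET	SC1	sidechain	50	0	CB,CG
MET	SC2	sidechain	51	0	SD,CE
PHE	MC1	mainchain	30	0	N,CA
PHE	MC2	mainchain	31	0	C,O
PHE	SC1	sidechain	52	0	CB,CG
PHE	SC2	sidechain	53	0	CD1,CD2,CE1,CE2,CZ
TYR	MC1	mainchain	30	0	N,CA
TYR	MC2	mainchain	31	0	C,O
TYR	SC1	sidechain	54	0	CB,CG
TYR	SC2	sidechain	55	0	CD1,CD2,CE1,CE2,CZ,OH
TRP	MC1	mainchain	30	0	N,CA
TRP	MC2	mainchain	31	0	C,O
TRP	SC1	sidechain	56	0	CB,CG
TRP	SC2	sidechain	57	0	CD1,CD2,NE1,CE2,CE3,CZ2,CZ3,CH2
ASP	MC1	mainchain	30	0	N,CA
ASP	MC2	mainchain	31	0	C,O
ASP	SC1	sidechain	58	0	CB
ASP	SC2	sidechain	59	-1	CG,OD1,OD2
GLU	MC1	mainchain	30	0	N,CA
GLU	MC2	mainchain	31	0	C,O
GLU	SC1	sidechain	60	0	CB,CG
GLU	SC2	sidechain	61	-1	CD,OE1,OE2
ASN	MC1	mainchain	30	0	N,CA
ASN	MC2	mainchain	31	0	C,O
ASN	SC1	sidechain	62	0	CB
ASN	SC2	sidechain	63	0	CG,OD1,ND2
GLN	MC1	mainchain	30	0	N,CA
GLN	MC2	mainchain	31	0	C,O
GLN	SC1	sidechain	64	0	CB,CG
GLN	SC2	sidechain	65	0	CD,OE1,NE2
LYS	MC1	mainchain	30	0	N,CA
LYS	MC2	mainchain	31	0	C,O
LYS	SC1	sidechain	66	0	CB,CG,CD
LYS	SC2	sidechain	67	1	CE,NZ
ARG	MC1	mainchain	30	0	N,CA
ARG	MC2	mainchain	31	0	C,O
ARG	SC1	sidechain	68	0	CB,CG,CD
ARG	SC2	sidechain	69	1	NE,CZ,NH1,NH2
HIS	MC1	mainchain	30	0	N,CA
HIS	MC2	mainchain	31	0	C,O
HIS	SC1	sidechain	70	0	CB,CG
HIS	SC2	sidechain	71	0	ND1,CD2,CE1,NE2
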
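# abmature united heavy-atom nonbonded parameter table, version 1
# charge: elementary charge units (hydrogens folded into bonded heavy atoms)
# rmin2: Lennard-Jones rmin/2 (A); eps: well depth (kcal/mol); radius: vdW radius for SASA (A)
# backbone group (N,CA,C,O) is net neutral; side chains carry the formal charge
# protonation: Arg/Lys +1, Asp/Glu -1, His neutral (NE2-H tautomer), free termini not modeled
residue	atom	charge	rmin2	eps	radius
ALA	N	-0.40	1.8240	0.1700	1.55
ALA	CA	 0.40	1.9080	0.1094	1.70
ALA	C	 0.55	1.9080	0.1094	1.70
ALA	O	-0.55	1.6612	0.2100	1.52
ALA	CB	 0.00	1.9080	0.1094	1.70
GLY	N	-0.40	1.8240	0.1700	1.55
GLY	CA	 0.40	1.9080	0.1094	1.70
GLY	C	 0.55	1.9080	0.1094	1.70
GLY	O	-0.55	1.6612	0.2100	1.52
SER	N	-0.40	1.8240	0.1700	1.55
SER	CA	 0.40	1.9080	0.1094	1.70
SER	C	 0.55	1.9080	0.1094	1.70
SER	O	-0.55	1.6612	0.2100	1.52
SER	CB	 0.25	1.9080	0.1094	1.70
SER	OG	-0.25	1.6612	0.2100	1.52
CYS	N	-0.40	1.8240	0.1700	1.55
CYS	CA	 0.40	1.9080	0.1094	1.70
CYS	C	 0.55	1.9080	0.1094	1.70
CYS	O	-0.55	1.6612	0.2100	1.52
CYS	CB	 0.12	1.9080	0.1094	1.70
CYS	SG	-0.12	2.0000	0.2500	1.80
THR	N	-0.40	1.8240	0.1700	1.55
THR	CA	 0.40	1.9080	0.1094	1.70
THR	C	 0.55	1.9080	0.1094	1.70
THR	O	-0.55	1.6612	0.2100	1.52
THR	CB	 0.25	1.9080	0.1094	1.70
THR	OG1	-0.25	1.6612	0.2100	1.52
THR	CG2	 0.00	1.9080	0.1094	1.70
VAL	N	-0.40	1.8240	0.1700	1.55
VAL	CA	 0.40	1.9080	0.1094	1.70
VAL	C	 0.55	1.9080	0.1094	1.70
VAL	O	-0.55	1.6612	0.2100	1.52
VAL	CB	 0.00	1.9080	0.1094	1.70
VAL	CG1	 0.00	1.9080	0.1094	1.70
VAL	CG2	 0.00	1.9080	0.1094	1.70
LEU	N	-0.40	1.8240	0.1700	1.55
LEU	CA	 0.40	1.9080	0.1094	1.70
LEU	C	 0.55	1.9080	0.1094	1.70
LEU	O	-0.55	1.6612	0.2100	1.52
LEU	CB	 0.00	1.9080	0.1094	1.70
LEU	CG	 0.00	1.9080	0.1094	1.70
LEU	CD1	 0.00	1.9080	0.1094	1.70
LEU	CD2	 0.00	1.9080	0.1094	1.70
ILE	N	-0.40	1.8240	0.1700	1.55
ILE	CA	 0.40	1.9080	0.1094	1.70
ILE	C	 0.55	1.9080	0.1094	1.70
ILE	O	-0.55	1.6612	0.2100	1.52
ILE	CB	 0.00	1.9080	0.1094	1.70
ILE	CG1	 0.00	1.9080	0.1094	1.70
ILE	CG2	 0.00	1.9080	0.1094	1.70
ILE	CD1	 0.00	1.9080	0.1094	1.70
MET	N	-0.40	1.8240	0.1700	1.55
MET	CA	 0.40	1.9080	0.1094	1.70
MET	C	 0.55	1.9080	0.1094	1.70
MET	O	-0.55	1.6612	0.2100	1.52
MET	CB	 0.00	1.9080	0.1094	1.70
MET	CG	 0.06	1.9080	0.1094	1.70
MET	SD	-0.12	2.0000	0.2500	1.80
MET	CE	 0.06	1.9080	0.1094	1.70
PHE	N	-0.40	1.8240	0.1700	1.55
PHE	CA	 0.40	1.9080	0.1094	1.70
PHE	C	 0.55	1.9080	0.1094	1.70
PHE	O	-0.55	1.6612	0.2100	1.52
PHE	CB	 0.00	1.9080	0.1094	1.70
PHE	CG	 0.00	1.9080	0.1094	1.70
PHE	CD1	 0.00	1.9080	0.1094	1.70
PHE	CD2	 0.00	1.9080	0.1094	1.70
PHE	CE1	 0.00	1.9080	0.1094	1.70
PHE	CE2	 0.00	1.9080	0.1094	1.70
PHE	CZ	 0.00	1.9080	0.1094	1.70
TYR	N	-0.40	1.8240	0.1700	1.55
TYR	CA	 0.40	1.9080	0.1094	1.70
TYR	C	 0.55	1.9080	0.1094	1.70
TYR	O	-0.55	1.6612	0.2100	1.52
TYR	CB	 0.00	1.9080	0.1094	1.70
TYR	CG	 0.00	1.9080	0.1094	1.70
TYR	CD1	 0.00	1.9080	0.1094	1.70
TYR	CD2	 0.00	1.9080	0.1094	1.70
TYR	CE1	 0.00	1.9080	0.1094	1.70
TYR	CE2	 0.00	1.9080	0.1094	1.70
TYR	CZ	 0.40	1.9080	0.1094	1.70
TYR	OH	-0.40	1.6612	0.2100	1.52
TRP	N	-0.40	1.8240	0.1700	1.55
TRP	CA	 0.40	1.9080	0.1094	1.70
TRP	C	 0.55	1.9080	0.1094	1.70
TRP	O	-0.55	1.6612	0.2100	1.52
TRP	CB	 0.00	1.9080	0.1094	1.70
TRP	CG	 0.00	1.9080	0.1094	1.70
TRP	CD1	 0.15	1.9080	0.1094	1.70
TRP	CD2	 0.00	1.9080	0.1094	1.70
TRP	NE1	-0.30	1.8240	0.1700	1.55
TRP	CE2	 0.15	1.9080	0.1094	1.70
TRP	CE3	 0.00	1.9080	0.1094	1.70
TRP	CZ2	 0.00	1.9080	0.1094	1.70
TRP	CZ3	 0.00	1.9080	0.1094	1.70
TRP	CH2	 0.00	1.9080	0.1094	1.70
ASP	N	-0.40	1.8240	0.1700	1.55
ASP	CA	 0.40	1.9080	0.1094	1.70
ASP	C	 0.55	1.9080	0.1094	1.70
ASP	O	-0.55	1.6612	0.2100	1.52
ASP	CB	-0.10	1.9080	0.1094	1.70
ASP	CG	 0.50	1.9080	0.1094	1.70
ASP	OD1	-0.70	1.6612	0.2100	1.52
ASP	OD2	-0.70	1.6612	0.2100	1.52
GLU	N	-0.40	1.8240	0.1700	1.55
GLU	CA	 0.40	1.9080	0.1094	1.70
GLU	C	 0.55	1.9080	0.1094	1.70
GLU	O	-0.55	1.6612	0.2100	1.52
GLU	CB	 0.00	1.9080	0.1094	1.70
GLU	CG	-0.10	1.9080	0.1094	1.70
GLU	CD	 0.50	1.9080	0.1094	1.70
GLU	OE1	-0.70	1.6612	0.2100	1.52
GLU	OE2	-0.70	1.6612	0.2100	1.52
ASN	N	-0.40	1.8240	0.1700	1.55
ASN	CA	 0.40	1.9080	0.1094	1.70
ASN	C	 0.55	1.9080	0.1094	1.70
ASN	O	-0.55	1.6612	0.2100	1.52
ASN	CB	 0.00	1.9080	0.1094	1.70
ASN	CG	 0.55	1.9080	0.1094	1.70
ASN	OD1	-0.55	1.6612	0.2100	1.52
ASN	ND2	 0.00	1.8240	0.1700	1.55
GLN	N	-0.40	1.8240	0.1700	1.55
GLN	CA	 0.40	1.9080	0.1094	1.70
GLN	C	 0.55	1.9080	0.1094	1.70
GLN	O	-0.55	1.6612	0.2100	1.52
GLN	CB	 0.00	1.9080	0.1094	1.70
GLN	CG	 0.00	1.9080	0.1094	1.70
GLN	CD	 0.55	1.9080	0.1094	1.70
GLN	OE1	-0.55	1.6612	0.2100	1.52
GLN	NE2	 0.00	1.8240	0.1700	1.55
LYS	N	-0.40	1.8240	0.1700	1.55
LYS	CA	 0.40	1.9080	0.1094	1.70
LYS	C	 0.55	1.9080	0.1094	1.70
LYS	O	-0.55	1.6612	0.2100	1.52
LYS	CB	 0.00	1.9080	0.1094	1.70
LYS	CG	 0.00	1.9080	0.1094	1.70
LYS	CD	 0.10	1.9080	0.1094	1.70
LYS	CE	 0.25	1.9080	0.1094	1.70
LYS	NZ	 0.65	1.8240	0.1700	1.55
ARG	N	-0.40	1.8240	0.1700	1.55
ARG	CA	 0.40	1.9080	0.1094	1.70
ARG	C	 0.55	1.9080	0.1094	1.70
ARG	O	-0.55	1.6612	0.2100	1.52
ARG	CB	 0.00	1.9080	0.1094	1.70
ARG	CG	 0.00	1.9080	0.1094	1.70
ARG	CD	 0.10	1.9080	0.1094	1.70
ARG	NE	-0.40	1.8240	0.1700	1.55
ARG	CZ	 0.70	1.9080	0.1094	1.70
ARG	NH1	 0.30	1.8240	0.1700	1.55
ARG	NH2	 0.30	1.8240	0.1700	1.55
HIS	N	-0.40	1.8240	0.1700	1.55
HIS	CA	 0.40	1.9080	0.1094	1.70
HIS	C	 0.55	1.9080	0.1094	1.70
HIS	O	-0.55	1.6612	0.2100	1.52
HIS	CB	 0.00	1.9080	0.1094	1.70
HIS	CG	 0.10	1.9080	0.1094	1.70
HIS	ND1	-0.40	1.8240	0.1700	1.55
HIS	CD2	 0.10	1.9080	0.1094	1.70
HIS	CE1	 0.30	1.9080	0.1094	1.70
HIS	NE2	-0.10	1.8240	0.1700	1.55
PRO	N	-0.40	1.8240	0.1700	1.55
PRO	CA	 0.40	1.9080	0.1094	1.70
PRO	C	 0.55	1.9080	0.1094	1.70
PRO	O	-0.55	1.6612	0.2100	1.52
PRO	CB	 0.00	1.9080	0.1094	1.70
PRO	CG	 0.00	1.9080	0.1094	1.70
PRO	CD	 0.00	1.9080	0.1094	1.70
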
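# Sybyl-style atom types for heavy atoms of the 20 canonical amino acids.
# Editable configuration: columns resname, atom, type (tab-separated).
resname	atom	type
ALA	N	N.am
ALA	CA	C.3
ALA	C	C.2
ALA	O	O.2
ALA	OXT	O.co2
ALA	CB	C.3
ARG	N	N.am
ARG	CA	C.3
ARG	C	C.2
ARG	O	O.2
ARG	OXT	O.co2
ARG	CB	C.3
ARG	CG	C.3
ARG	CD	C.3
ARG	NE	N.pl3
ARG	CZ	C.2
ARG	NH1	N.pl3
ARG	NH2	N.pl3
ASN	N	N.am
ASN	CA	C.3
ASN	C	C.2
ASN	O	O.2
ASN	OXT	O.co2
ASN	CB	C.3
ASN	CG	C.2
ASN	OD1	O.2
ASN	ND2	N.am
ASP	N	N.am
ASP	CA	C.3
ASP	C	C.2
ASP	O	O.2
ASP	OXT	O.co2
ASP	CB	C.3
ASP	CG	C.2
ASP	OD1	O.co2
ASP	OD2	O.co2
CYS	N	N.am
CYS	CA	C.3
CYS	C	C.2
CYS	O	O.2
CYS	OXT	O.co2
CYS	CB	C.3
CYS	SG	S.3
GLN	N	N.am
GLN	CA	C.3
GLN	C	C.2
GLN	O	O.2
GLN	OXT	O.co2
GLN	CB	C.3
GLN	CG	C.3
GLN	CD	C.2
GLN	OE1	O.2
GLN	NE2	N.am
GLU	N	N.am
GLU	CA	C.3
GLU	C	C.2
GLU	O	O.2
GLU	OXT	O.co2
GLU	CB	C.3
GLU	CG	C.3
GLU	CD	C.2
GLU	OE1	O.co2
GLU	OE2	O.co2
GLY	N	N.am
GLY	CA	C.3
GLY	C	C.2
GLY	O	O.2
GLY	OXT	O.co2
HIS	N	N.am
HIS	CA	C.3
HIS	C	C.2
HIS	O	O.2
HIS	OXT	O.co2
HIS	CB	C.3
HIS	CG	C.ar
HIS	ND1	N.ar
HIS	CD2	C.ar
HIS	CE1	C.ar
HIS	NE2	N.ar
ILE	N	N.am
ILE	CA	C.3
ILE	C	C.2
ILE	O	O.2
ILE	OXT	O.co2
ILE	CB	C.3
ILE	CG1	C.3
ILE	CG2	C.3
ILE	CD1	C.3
ILE	CD	C.3
LEU	N	N.am
LEU	CA	C.3
LEU	C	C.2
LEU	O	O.2
LEU	OXT	O.co2
LEU	CB	C.3
LEU	CG	C.3
LEU	CD1	C.3
LEU	CD2	C.3
LYS	N	N.am
LYS	CA	C.3
LYS	C	C.2
LYS	O	O.2
LYS	OXT	O.co2
LYS	CB	C.3
LYS	CG	C.3
LYS	CD	C.3
LYS	CE	C.3
LYS	NZ	N.3
MET	N	N.am
MET	CA	C.3
MET	C	C.2
MET	O	O.2
MET	OXT	O.co2
MET	CB	C.3
MET	CG	C.3
MET	SD	S.3
MET	CE	C.3
PHE	N	N.am
PHE	CA	C.3
PHE	C	C.2
PHE	O	O.2
PHE	OXT	O.co2
PHE	CB	C.3
PHE	CG	C.ar
PHE	CD1	C.ar
PHE	CD2	C.ar
PHE	CE1	C.ar
PHE	CE2	C.ar
PHE	CZ	C.ar
PRO	N	N.am
PRO	CA	C.3
PRO	C	C.2
PRO	O	O.2
PRO	OXT	O.co2
PRO	CB	C.3
PRO	CG	C.3
PRO	CD	C.3
SER	N	N.am
SER	CA	C.3
SER	C	C.2
SER	O	O.2
SER	OXT	O.co2
SER	CB	C.3
SER	OG	O.3
THR	N	N.am
THR	CA	C.3
THR	C	C.2
THR	O	O.2
THR	OXT	O.co2
THR	CB	C.3
THR	OG1	O.3
THR	CG2	C.3
TRP	N	N.am
TRP	CA	C.3
TRP	C	C.2
TRP	O	O.2
TRP	OXT	O.co2
TRP	CB	C.3
TRP	CG	C.ar
TRP	CD1	C.ar
TRP	CD2	C.ar
TRP	NE1	N.ar
TRP	CE2	C.ar
TRP	CE3	C.ar
TRP	CZ2	C.ar
TRP	CZ3	C.ar
TRP	CH2	C.ar
TYR	N	N.am
TYR	CA	C.3
TYR	C	C.2
TYR	O	O.2
TYR	OXT	O.co2
TYR	CB	C.3
TYR	CG	C.ar
TYR	CD1	C.ar
TYR	CD2	C.ar
TYR	CE1	C.ar
TYR	CE2	C.ar
TYR	CZ	C.ar
TYR	OH	O.3
VAL	N	N.am
VAL	CA	C.3
VAL	C	C.2
VAL	O	O.2
VAL	OXT	O.co2
VAL	CB	C.3
VAL	CG1	C.3
VAL	CG2	C.3
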
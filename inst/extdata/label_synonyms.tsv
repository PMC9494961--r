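synonym	label
COI	COI
CO1	COI
COX1	COI
COXI	COI
COX-I	COI
COII	COII
CO2	COII
COX2	COII
COXII	COII
COIII	COIII
CO3	COIII
COX3	COIII
COXIII	COIII
CYTB	CYTB
COB	CYTB
CYB	CYTB
ATP6	ATP6
ATPASE6	ATP6
ATP8	ATP8
ATPASE8	ATP8
ND1	ND1
NAD1	ND1
NADH1	ND1
ND2	ND2
NAD2	ND2
NADH2	ND2
ND3	ND3
NAD3	ND3
NADH3	ND3
ND4	ND4
NAD4	ND4
NADH4	ND4
ND4L	ND4L
NAD4L	ND4L
ND5	ND5
NAD5	ND5
NADH5	ND5
ND6	ND6
NAD6	ND6
NADH6	ND6
12SRRNA	12S
12SRIBOSOMALRNA	12S
RRNS	12S
SRRNA	12S
S-RRNA	12S
SMALLSUBUNITRIBOSOMALRNA	12S
16SRRNA	16S
16SRIBOSOMALRNA	16S
RRNL	16S
LRRNA	16S
L-RRNA	16S
LARGESUBUNITRIBOSOMALRNA	16S
D-LOOP	CR
DLOOP	CR
CONTROLREGION	CR
CR	CR
CR1	CR1
CR2	CR2
CONTROLREGION1	CR1
CONTROLREGION2	CR2
OL	OL
O_L	OL
REP_ORIGIN	OL
OLREP	OL
MISC_FEATURE	NCR
ORIGINOFL-STRANDREPLICATION	OL
L-STRANDORIGIN	OL
NCR	NCR
NONCODINGREGION	NCR
NON-CODINGREGION	NCR
TRNA-PHE	F
TRNF	F
TRNA-VAL	V
TRNV	V
TRNA-LEU(UUR)	L(UUR)
TRNA-LEU(TAA)	L(UUR)
TRNL2	L(UUR)
TRNL(UUR)	L(UUR)
TRNA-LEU(CUN)	L(CUN)
TRNA-LEU(TAG)	L(CUN)
TRNL1	L(CUN)
TRNL(CUN)	L(CUN)
TRNA-ILE	I
TRNI	I
TRNA-GLN	Q
TRNQ	Q
TRNA-MET	M
TRNM	M
TRNA-TRP	W
TRNW	W
TRNA-ALA	A
TRNA2	A
TRNA-ASN	N
TRNN	N
TRNA-CYS	C
TRNC	C
TRNA-TYR	Y
TRNY	Y
TRNA-SER(UCN)	S(UCN)
TRNA-SER(TGA)	S(UCN)
TRNS2	S(UCN)
TRNS(UCN)	S(UCN)
TRNA-SER(AGY)	S(AGY)
TRNA-SER(AGN)	S(AGY)
TRNA-SER(GCT)	S(AGY)
TRNS1	S(AGY)
TRNS(AGY)	S(AGY)
TRNA-ASP	D
TRND	D
TRNA-LYS	K
TRNK	K
TRNA-GLY	G
TRNG	G
TRNA-ARG	R
TRNR	R
TRNA-HIS	H
TRNH	H
TRNA-GLU	E
TRNE	E
TRNA-THR	T
TRNT	T
TRNA-PRO	P
TRNP	P
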
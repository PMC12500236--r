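accession,division,category
COL1A1,core matrisome,collagens
COL1A2,core matrisome,collagens
COL2A1,core matrisome,collagens
COL3A1,core matrisome,collagens
COL4A1,core matrisome,collagens
COL4A2,core matrisome,collagens
COL5A1,core matrisome,collagens
COL6A1,core matrisome,collagens
COL6A2,core matrisome,collagens
COL6A3,core matrisome,collagens
COL11A1,core matrisome,collagens
COL12A1,core matrisome,collagens
COL18A1,core matrisome,collagens
FN1,core matrisome,ECM glycoproteins
LAMA1,core matrisome,ECM glycoproteins
LAMA5,core matrisome,ECM glycoproteins
LAMB1,core matrisome,ECM glycoproteins
LAMC1,core matrisome,ECM glycoproteins
LAMC2,core matrisome,ECM glycoproteins
TNC,core matrisome,ECM glycoproteins
THBS1,core matrisome,ECM glycoproteins
THBS2,core matrisome,ECM glycoproteins
FBN1,core matrisome,ECM glycoproteins
FBLN1,core matrisome,ECM glycoproteins
FBLN2,core matrisome,ECM glycoproteins
EMILIN1,core matrisome,ECM glycoproteins
NID1,core matrisome,ECM glycoproteins
NID2,core matrisome,ECM glycoproteins
VTN,core matrisome,ECM glycoproteins
ELN,core matrisome,ECM glycoproteins
TGFBI,core matrisome,ECM glycoproteins
POSTN,core matrisome,ECM glycoproteins
SPARC,core matrisome,ECM glycoproteins
HSPG2,core matrisome,proteoglycans
ACAN,core matrisome,proteoglycans
BGN,core matrisome,proteoglycans
DCN,core matrisome,proteoglycans
LUM,core matrisome,proteoglycans
VCAN,core matrisome,proteoglycans
PRELP,core matrisome,proteoglycans
OGN,core matrisome,proteoglycans
MMP2,matrisome-associated,ECM regulators
MMP9,matrisome-associated,ECM regulators
MMP14,matrisome-associated,ECM regulators
TIMP1,matrisome-associated,ECM regulators
TIMP2,matrisome-associated,ECM regulators
LOX,matrisome-associated,ECM regulators
LOXL1,matrisome-associated,ECM regulators
LOXL2,matrisome-associated,ECM regulators
PLOD1,matrisome-associated,ECM regulators
PLOD2,matrisome-associated,ECM regulators
P4HA1,matrisome-associated,ECM regulators
SERPINE1,matrisome-associated,ECM regulators
SERPINH1,matrisome-associated,ECM regulators
PCOLCE,matrisome-associated,ECM regulators
PCOLCE2,matrisome-associated,ECM regulators
CTSK,matrisome-associated,ECM regulators
ANXA1,matrisome-associated,ECM-affiliated proteins
ANXA2,matrisome-associated,ECM-affiliated proteins
ANXA5,matrisome-associated,ECM-affiliated proteins
LGALS1,matrisome-associated,ECM-affiliated proteins
LGALS3,matrisome-associated,ECM-affiliated proteins
PLXNB2,matrisome-associated,ECM-affiliated proteins
SEMA3C,matrisome-associated,ECM-affiliated proteins
C1QB,matrisome-associated,ECM-affiliated proteins
TGFB1,matrisome-associated,secreted factors
VEGFA,matrisome-associated,secreted factors
CTGF,matrisome-associated,secreted factors
S100A4,matrisome-associated,secreted factors
S100A6,matrisome-associated,secreted factors
WNT5A,matrisome-associated,secreted factors
EGFL7,matrisome-associated,secreted factors
HGF,matrisome-associated,secreted factors
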
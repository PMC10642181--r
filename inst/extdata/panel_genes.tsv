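symbol	refseq	locus	risk_level	phenotype	lof_mechanism	exon_boundaries
APC	NM_000038.6	5q22.2	high	Familial adenomatous polyposis (FAP)/attenuated FAP; gastric adenocarcinoma and proximal polyposis of the stomach	TRUE
BMPR1A	NM_004329.3	10q23.2	high	Juvenile polyposis syndrome; hereditary mixed polyposis syndrome; pulmonary arterial hypertension	TRUE
EPCAM	NM_002354.3	2p21	high	Lynch syndrome	TRUE
MLH1	NM_000249.4	3p21.3	high	Lynch syndrome; mismatch repair cancer syndrome 1; hereditary breast carcinoma	TRUE	1731
MSH2	NM_000251.3	2p22-p21	high	Lynch syndrome; mismatch repair cancer syndrome 1; hereditary breast carcinoma	TRUE
MSH6	NM_000179.3	2p16	high	Lynch syndrome; mismatch repair cancer syndrome 1; hereditary breast carcinoma	TRUE
MUTYH	NM_001128425.2	1p34.1	high	MUTYH-associated polyposis; FAP II	TRUE
PMS2	NM_000535.7	7p22	high	Lynch syndrome; mismatch repair cancer syndrome I; hereditary breast carcinoma	TRUE
POLD1	NM_001256849.1	19q13.33	risk	Polymerase proofreading-associated polyposis	FALSE
POLE	NM_006231.4	12q24.33	risk	Polymerase proofreading-associated polyposis	FALSE
PTEN	NM_000314.8	10q23.31	high	PTEN hamartoma tumor syndrome (Cowden syndrome/Bannayan-Riley-Ruvalcaba syndrome)	TRUE
SMAD4	NM_005359.6	18q21.2	high	Juvenile polyposis syndrome (JPS); JPS/hereditary hemorrhagic telangiectasia syndrome	TRUE
STK11	NM_000455.5	19p13.3	high	Peutz-Jeghers syndrome	TRUE
TP53	NM_000546.5	17p13.1	lower	Li-Fraumeni syndrome	TRUE
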
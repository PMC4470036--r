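line	sex	grade	instability_group
253J	F	G4	Intermediate
5637	M	G2	Intermediate
575A	M	G3	Intermediate
639V	M	G3	High
92-1	F	G3	Intermediate
96-1	M	G2/3	Intermediate
97-1	M	G1/2	Low
97-18	M	G3	High
97-24	M	G3	High
97-7	M	G2/3	High
BC61	M	G2	Low
HT1197	M	G4
HT1376	F	G3	Low
HU456	M	G1	Intermediate
J82	M	G3	Intermediate
JON	unknown
KK47	M	G1	High
LGWO1 G600	unknown		Low
MGH-U3	M	G1	Low
MGH-U4	M	G1	Low
PSI	M	G3
RT112	F	G2	Low
RT4	M	G1	Low
SCaBER	M		Intermediate
SW-1710	F		High
SW-800	M		Low
SW-850	unknown
SW-780	F	G1	Low
T24	F	G3	Low
TCCSUP	F	G4	Intermediate
UM-UC-1	M	G2	Intermediate
UM-UC-2	M	CIS
UM-UC-3	M		High
UM-UC-4	F		High
UM-UC-5	F		Intermediate
UM-UC-6	M		Low
UM-UC-7	M		Intermediate
UM-UC-9	unknown		Intermediate
UM-UC-10	unknown
UM-UC-11	unknown		High
UM-UC-12	M		High
UM-UC-13	M		High
UM-UC-14	M		Low
UM-UC-15	unknown
UM-UC-17	unknown		Intermediate
UM-UC-18	unknown		High
VM-CUB-1	M	G2	High
VM-CUB-2	M		High
VM-CUB-3	M	G3	Low
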
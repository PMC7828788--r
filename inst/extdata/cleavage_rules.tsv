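enzyme	clause	action	slot	mode	residues
trypsin	1	cut	P1	allowed	KR
trypsin	1	cut	P1'	forbidden	P
trypsin	2	cut	P2	allowed	W
trypsin	2	cut	P1	allowed	K
trypsin	2	cut	P1'	allowed	P
trypsin	3	cut	P2	allowed	M
trypsin	3	cut	P1	allowed	R
trypsin	3	cut	P1'	allowed	P
trypsin	4	block	P2	allowed	CD
trypsin	4	block	P1	allowed	K
trypsin	4	block	P1'	allowed	D
trypsin	5	block	P2	allowed	C
trypsin	5	block	P1	allowed	K
trypsin	5	block	P1'	allowed	HY
trypsin	6	block	P2	allowed	C
trypsin	6	block	P1	allowed	R
trypsin	6	block	P1'	allowed	K
trypsin	7	block	P2	allowed	R
trypsin	7	block	P1	allowed	R
trypsin	7	block	P1'	allowed	HR
chymotrypsin_high	1	cut	P1	allowed	FY
chymotrypsin_high	1	cut	P1'	forbidden	P
chymotrypsin_high	2	cut	P1	allowed	W
chymotrypsin_high	2	cut	P1'	forbidden	MP
chymotrypsin_low	1	cut	P1	allowed	FLM
chymotrypsin_low	1	cut	P1'	forbidden	PY
chymotrypsin_low	2	cut	P1	allowed	W
chymotrypsin_low	2	cut	P1'	forbidden	MP
chymotrypsin_low	3	cut	P1	allowed	Y
chymotrypsin_low	3	cut	P1'	forbidden	P
chymotrypsin_low	4	cut	P1	allowed	H
chymotrypsin_low	4	cut	P1'	forbidden	DMPW
pepsin_ph13	1	cut	P3	forbidden	HKR
pepsin_ph13	1	cut	P2	forbidden	P
pepsin_ph13	1	cut	P1	forbidden	R
pepsin_ph13	1	cut	P1'	allowed	FL
pepsin_ph13	1	cut	P2'	forbidden	P
pepsin_ph13	2	cut	P3	forbidden	HKR
pepsin_ph13	2	cut	P2	forbidden	P
pepsin_ph13	2	cut	P1	allowed	FL
pepsin_ph13	2	cut	P2'	forbidden	P
pepsin_ph2	1	cut	P3	forbidden	HKR
pepsin_ph2	1	cut	P2	forbidden	P
pepsin_ph2	1	cut	P1	forbidden	R
pepsin_ph2	1	cut	P1'	allowed	FLWY
pepsin_ph2	1	cut	P2'	forbidden	P
pepsin_ph2	2	cut	P3	forbidden	HKR
pepsin_ph2	2	cut	P2	forbidden	P
pepsin_ph2	2	cut	P1	allowed	FLWY
pepsin_ph2	2	cut	P2'	forbidden	P
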
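protein_id	allergen_label	start	end	sequence	source	note
P00711	Bos d 4	75	98	NNKIWCKDDQNPHSSNICNISCDK	IV	Table 2 prints this peptide without H at 76-98; the 24-mer with H (span 24 = length 24) is carried
P02754	Bos d 5	139	163	LVRTPEVDDEALEKFDKALKALPM	IV	printed span 139-163 covers 25 residues but the peptide has 24; true location 138-161
P02662	Bos d 9	108	131	GYLEQLLRLKKYKVPQLEIVPNSA	IV	
P02662	Bos d 9	137	160	SMKEGIHAQQKEPMIGVNQELAYF	IV	
P02662	Bos d 9	195	208	SDIPNPIGSENSEK	IV	Table 3 prints SDIPNPIGSENSK (13 aa) for this span; the 14-mer agreeing with Tables 1 and 4 is carried
P02662	Bos d 9	94	116	QKHIQKEDVPSERYLGYLEQLLRL	IV	printed span 94-116 covers 23 residues but the peptide has 24; true location 93-116
P04258	Collagen alpha-1(III)	266	289	GPVGNPGPAGPAGPRGEVGLPGLS	IV	
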
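peptide_id	source	drb1_weak	dq_weak	dp_weak	drb1_strong	dq_strong	dp_strong
DTQAIVQNNDSTE	IS	7	1	5	1	4	2
SSNICNISCDK	IS	0	1	0	0	4	0
ENSAEPEQS	IS	0	5	3	0	0	0
QECCQAEDK	IS	0	3	0	0	0	0
ICDNQDTISSK	IS	2	3	3	9	2	3
DAIPENLPPL	IS	0	0	0	0	5	7
VPQVSTPTL	IS	6	0	3	3	5	4
CCTKPESER	IS	0	4	1	0	1	0
DIGSESTEDQAM	IS	6	0	5	2	5	1
EAESISSSEEIVPNSVEQK	IS	0	0	1	8	5	6
EIVPNSAEER	IS	3	0	6	2	5	1
SDIPNPIGSENSEK	IS	8	0	6	0	5	1
VSSSEESIISQET	IS	2	0	2	1	5	5
SIGSSSEESAEVATEEVK	IS	5	0	4	3	5	3
NAVPITPTL	IS	0	1	1	0	4	0
NVPGEIVES	IS	0	3	1	0	2	0
SSSEESITR	IS	0	1	1	0	0	0
QSEEQQQTEDE	IS	0	5	1	0	0	0
PFPGPIPNSL	IS	6	1	0	3	4	7
TQTPVVVPPF	IS	0	0	7	0	5	0
GAQEQNQEQPIR	IS	0	0	5	0	5	2
SCQAQPTTM	IS	0	0	7	0	5	0
TEIPTINTIASGEPTSTPTTEAVESTVAT	IS	1	0	0	8	5	7
EDSPEVIESPPEINTVQVTSTAV	IS	4	0	0	7	5	7
NNKIWCKDDQNPHSSNICNISCDK	IV	1	1	4	7	4	3
LVRTPEVDDEALEKFDKALKALPM	IV	3	0	0	9	5	7
GYLEQLLRLKKYKVPQLEIVPNSA	IV	0	0	0	12	5	7
SMKEGIHAQQKEPMIGVNQELAYF	IV	3	0	0	8	5	7
SDIPNPIGSENSEK	IV	8	0	6	0	5	1
QKHIQKEDVPSERYLGYLEQLLRL	IV	1	0	0	8	5	7
GPVGNPGPAGPAGPRGEVGLPGLS	IV	6	0	4	2	5	3
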
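peptide_id	source	allele	locus	scale	value	censored
DTQAIVQNNDSTE	IS	DRB1*01:01	DRB1	ic50_nM	121.63	FALSE
DTQAIVQNNDSTE	IS	DQ7	DQ	ic50_nM	101.36	FALSE
DTQAIVQNNDSTE	IS	DQ8	DQ	ic50_nM	76.41	FALSE
DTQAIVQNNDSTE	IS	DRB1*03:01	DRB1	ic50_nM	93.56	FALSE
DTQAIVQNNDSTE	IS	DRB1*14:19	DRB1	ic50_nM	96.68	FALSE
DTQAIVQNNDSTE	IS	DRB1*14:21	DRB1	ic50_nM	134.1	FALSE
SSNICNISCDK	IS	DRB1*01:01	DRB1	ic50_nM	502.78	FALSE
SSNICNISCDK	IS	DQ7	DQ	ic50_nM	308.52	FALSE
SSNICNISCDK	IS	DQ8	DQ	ic50_nM	291.38	FALSE
SSNICNISCDK	IS	DRB1*03:01	DRB1	ic50_nM	365.66	FALSE
SSNICNISCDK	IS	DRB1*14:19	DRB1	ic50_nM	445.64	FALSE
SSNICNISCDK	IS	DRB1*14:21	DRB1	ic50_nM	462.78	FALSE
ICDNQDTISSK	IS	DRB1*01:01	DRB1	ic50_nM	462.78	FALSE
ICDNQDTISSK	IS	DQ7	DQ	ic50_nM	514.2	FALSE
ICDNQDTISSK	IS	DQ8	DQ	ic50_nM	354.23	FALSE
ICDNQDTISSK	IS	DRB1*03:01	DRB1	ic50_nM	234.25	FALSE
ICDNQDTISSK	IS	DRB1*14:19	DRB1	ic50_nM	359.94	FALSE
ICDNQDTISSK	IS	DRB1*14:21	DRB1	ic50_nM	468.5	FALSE
DIGSESTEDQAM	IS	DRB1*01:01	DRB1	ic50_nM	266.88	FALSE
DIGSESTEDQAM	IS	DQ7	DQ	ic50_nM	240.19	FALSE
DIGSESTEDQAM	IS	DQ8	DQ	ic50_nM	68.2	FALSE
DIGSESTEDQAM	IS	DRB1*03:01	DRB1	ic50_nM	169.02	FALSE
DIGSESTEDQAM	IS	DRB1*14:19	DRB1	ic50_nM	287.63	FALSE
DIGSESTEDQAM	IS	DRB1*14:21	DRB1	ic50_nM	287.63	FALSE
EAESISSSEEIVPNSVEQK	IS	DRB1*01:01	DRB1	ic50_nM	462.53	FALSE
EAESISSSEEIVPNSVEQK	IS	DQ7	DQ	ic50_nM	107.92	FALSE
EAESISSSEEIVPNSVEQK	IS	DQ8	DQ	ic50_nM	16.96	FALSE
EAESISSSEEIVPNSVEQK	IS	DRB1*03:01	DRB1	ic50_nM	174.73	FALSE
EAESISSSEEIVPNSVEQK	IS	DRB1*14:19	DRB1	ic50_nM	277.52	FALSE
EAESISSSEEIVPNSVEQK	IS	DRB1*14:21	DRB1	ic50_nM	426.55	FALSE
SDIPNPIGSENSEK	IS	DRB1*01:01	DRB1	ic50_nM	96.91	FALSE
SDIPNPIGSENSEK	IS	DQ7	DQ	ic50_nM	67.84	FALSE
SDIPNPIGSENSEK	IS	DQ8	DQ	ic50_nM	48.46	FALSE
SDIPNPIGSENSEK	IS	DRB1*03:01	DRB1	ic50_nM	99.07	FALSE
SDIPNPIGSENSEK	IS	DRB1*14:19	DRB1	ic50_nM	105.53	FALSE
SDIPNPIGSENSEK	IS	DRB1*14:21	DRB1	ic50_nM	106.6	FALSE
VSSSEESIISQET	IS	DRB1*01:01	DRB1	ic50_nM	124.75	FALSE
VSSSEESIISQET	IS	DQ7	DQ	ic50_nM	46.78	FALSE
VSSSEESIISQET	IS	DQ8	DQ	ic50_nM	1.72	FALSE
VSSSEESIISQET	IS	DRB1*03:01	DRB1	ic50_nM	102.92	FALSE
VSSSEESIISQET	IS	DRB1*14:19	DRB1	ic50_nM	145.02	FALSE
VSSSEESIISQET	IS	DRB1*14:21	DRB1	ic50_nM	146.58	FALSE
SIGSSSEESAEVATEEVK	IS	DRB1*01:01	DRB1	ic50_nM	272.29	FALSE
SIGSSSEESAEVATEEVK	IS	DQ7	DQ	ic50_nM	47.35	FALSE
SIGSSSEESAEVATEEVK	IS	DQ8	DQ	ic50_nM	0.53	FALSE
SIGSSSEESAEVATEEVK	IS	DRB1*03:01	DRB1	ic50_nM	260.45	FALSE
SIGSSSEESAEVATEEVK	IS	DRB1*14:19	DRB1	ic50_nM	293.01	FALSE
SIGSSSEESAEVATEEVK	IS	DRB1*14:21	DRB1	ic50_nM	295.97	FALSE
QSEEQQQTEDE	IS	DRB1*01:01	DRB1	ic50_nM	531.34	FALSE
QSEEQQQTEDE	IS	DQ7	DQ	ic50_nM	508.49	FALSE
QSEEQQQTEDE	IS	DQ8	DQ	ic50_nM	165.69	FALSE
QSEEQQQTEDE	IS	DRB1*03:01	DRB1	ic50_nM	565.62	FALSE
QSEEQQQTEDE	IS	DRB1*14:19	DRB1	ic50_nM	571.34	FALSE
QSEEQQQTEDE	IS	DRB1*14:21	DRB1	ic50_nM	571.34	FALSE
GAQEQNQEQPIR	IS	DRB1*01:01	DRB1	ic50_nM	278.74	FALSE
GAQEQNQEQPIR	IS	DQ7	DQ	ic50_nM	281.7	FALSE
GAQEQNQEQPIR	IS	DQ8	DQ	ic50_nM	204.61	FALSE
GAQEQNQEQPIR	IS	DRB1*03:01	DRB1	ic50_nM	275.77	FALSE
GAQEQNQEQPIR	IS	DRB1*14:19	DRB1	ic50_nM	278.74	FALSE
GAQEQNQEQPIR	IS	DRB1*14:21	DRB1	ic50_nM	287.63	FALSE
TEIPTINTIASGEPTSTPTTEAVESTVAT	IS	DRB1*01:01	DRB1	ic50_nM	5000	TRUE
TEIPTINTIASGEPTSTPTTEAVESTVAT	IS	DQ7	DQ	ic50_nM	4253.87	FALSE
TEIPTINTIASGEPTSTPTTEAVESTVAT	IS	DQ8	DQ	ic50_nM	5000	TRUE
TEIPTINTIASGEPTSTPTTEAVESTVAT	IS	DRB1*03:01	DRB1	ic50_nM	5000	TRUE
TEIPTINTIASGEPTSTPTTEAVESTVAT	IS	DRB1*14:19	DRB1	ic50_nM	5000	TRUE
TEIPTINTIASGEPTSTPTTEAVESTVAT	IS	DRB1*14:21	DRB1	ic50_nM	5000	TRUE
EDSPEVIESPPEINTVQVTSTAV	IS	DRB1*01:01	DRB1	ic50_nM	973.05	FALSE
EDSPEVIESPPEINTVQVTSTAV	IS	DQ7	DQ	ic50_nM	858.58	FALSE
EDSPEVIESPPEINTVQVTSTAV	IS	DQ8	DQ	ic50_nM	629.62	FALSE
EDSPEVIESPPEINTVQVTSTAV	IS	DRB1*03:01	DRB1	ic50_nM	2146.44	FALSE
EDSPEVIESPPEINTVQVTSTAV	IS	DRB1*14:19	DRB1	ic50_nM	2432.64	FALSE
EDSPEVIESPPEINTVQVTSTAV	IS	DRB1*14:21	DRB1	ic50_nM	2690.21	FALSE
NNKIWCKDDQNPHSSNICNISCDK	IV	DRB1*01:01	DRB1	ic50_nM	4244.21	FALSE
NNKIWCKDDQNPHSSNICNISCDK	IV	DQ7	DQ	ic50_nM	3480.25	FALSE
NNKIWCKDDQNPHSSNICNISCDK	IV	DQ8	DQ	ic50_nM	3862.23	FALSE
NNKIWCKDDQNPHSSNICNISCDK	IV	DRB1*03:01	DRB1	ic50_nM	3352.93	FALSE
NNKIWCKDDQNPHSSNICNISCDK	IV	DRB1*14:19	DRB1	ic50_nM	3650.02	FALSE
NNKIWCKDDQNPHSSNICNISCDK	IV	DRB1*14:21	DRB1	ic50_nM	4116.89	FALSE
LVRTPEVDDEALEKFDKALKALPM	IV	DRB1*01:01	DRB1	ic50_nM	1952.34	FALSE
LVRTPEVDDEALEKFDKALKALPM	IV	DQ7	DQ	ic50_nM	3268.04	FALSE
LVRTPEVDDEALEKFDKALKALPM	IV	DQ8	DQ	ic50_nM	1273.26	FALSE
LVRTPEVDDEALEKFDKALKALPM	IV	DRB1*03:01	DRB1	ic50_nM	2588.97	FALSE
LVRTPEVDDEALEKFDKALKALPM	IV	DRB1*14:19	DRB1	ic50_nM	1527.92	FALSE
LVRTPEVDDEALEKFDKALKALPM	IV	DRB1*14:21	DRB1	ic50_nM	1315.71	FALSE
GYLEQLLRLKKYKVPQLEIVPNSA	IV	DRB1*01:01	DRB1	ic50_nM	1145.94	FALSE
GYLEQLLRLKKYKVPQLEIVPNSA	IV	DQ7	DQ	ic50_nM	3013.39	FALSE
GYLEQLLRLKKYKVPQLEIVPNSA	IV	DQ8	DQ	ic50_nM	3310.49	FALSE
GYLEQLLRLKKYKVPQLEIVPNSA	IV	DRB1*03:01	DRB1	ic50_nM	2970.95	FALSE
GYLEQLLRLKKYKVPQLEIVPNSA	IV	DRB1*14:19	DRB1	ic50_nM	1612.8	FALSE
GYLEQLLRLKKYKVPQLEIVPNSA	IV	DRB1*14:21	DRB1	ic50_nM	373.49	FALSE
SMKEGIHAQQKEPMIGVNQELAYF	IV	DRB1*01:01	DRB1	ic50_nM	3437.81	FALSE
SMKEGIHAQQKEPMIGVNQELAYF	IV	DQ7	DQ	ic50_nM	3310.49	FALSE
SMKEGIHAQQKEPMIGVNQELAYF	IV	DQ8	DQ	ic50_nM	1230.82	FALSE
SMKEGIHAQQKEPMIGVNQELAYF	IV	DRB1*03:01	DRB1	ic50_nM	1527.92	FALSE
SMKEGIHAQQKEPMIGVNQELAYF	IV	DRB1*14:19	DRB1	ic50_nM	2376.76	FALSE
SMKEGIHAQQKEPMIGVNQELAYF	IV	DRB1*14:21	DRB1	ic50_nM	1527.82	FALSE
SDIPNPIGSENSEK	IV	DRB1*01:01	DRB1	ic50_nM	96.91	FALSE
SDIPNPIGSENSEK	IV	DQ7	DQ	ic50_nM	67.84	FALSE
SDIPNPIGSENSEK	IV	DQ8	DQ	ic50_nM	48.46	FALSE
SDIPNPIGSENSEK	IV	DRB1*03:01	DRB1	ic50_nM	99.07	FALSE
SDIPNPIGSENSEK	IV	DRB1*14:19	DRB1	ic50_nM	105.53	FALSE
SDIPNPIGSENSEK	IV	DRB1*14:21	DRB1	ic50_nM	106.6	FALSE
QKHIQKEDVPSERYLGYLEQLLRL	IV	DRB1*01:01	DRB1	ic50_nM	1909.9	FALSE
QKHIQKEDVPSERYLGYLEQLLRL	IV	DQ7	DQ	ic50_nM	3055.83	FALSE
QKHIQKEDVPSERYLGYLEQLLRL	IV	DQ8	DQ	ic50_nM	1867.45	FALSE
QKHIQKEDVPSERYLGYLEQLLRL	IV	DRB1*03:01	DRB1	ic50_nM	2037.22	FALSE
QKHIQKEDVPSERYLGYLEQLLRL	IV	DRB1*14:19	DRB1	ic50_nM	2970.95	FALSE
QKHIQKEDVPSERYLGYLEQLLRL	IV	DRB1*14:21	DRB1	ic50_nM	2291.87	FALSE
GPVGNPGPAGPAGPRGEVGLPGLS	IV	DRB1*01:01	DRB1	ic50_nM	2776.07	FALSE
GPVGNPGPAGPAGPRGEVGLPGLS	IV	DQ7	DQ	ic50_nM	343.43	FALSE
GPVGNPGPAGPAGPRGEVGLPGLS	IV	DQ8	DQ	ic50_nM	2747.45	FALSE
GPVGNPGPAGPAGPRGEVGLPGLS	IV	DRB1*03:01	DRB1	ic50_nM	2833.31	FALSE
GPVGNPGPAGPAGPRGEVGLPGLS	IV	DRB1*14:19	DRB1	ic50_nM	2861.93	FALSE
GPVGNPGPAGPAGPRGEVGLPGLS	IV	DRB1*14:21	DRB1	ic50_nM	2861.93	FALSE
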
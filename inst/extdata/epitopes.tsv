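protein_id	kind	start	end	sequence	citation
P00711	Tcell	58	75	QAIVQNNDSTEYGLFQIN	curated
P00711	Tcell	74	91	INNKIWCKDDQNPHSSNI	curated
P00711	IgE	36	77	GYGGVSLPEWVCTTFHTSGYDTQAIVQNNDSTEYGLFQINNK	curated
P00711	IgE	79	98		curated
P02754	Tcell	113	133	TDYKKYLLFCMENSAEPEQSL	curated
P02769	Tcell	317	336		curated
P02662	Tcell	58	81	DIGSESTEDQAMEDIKQMEAESIS	curated
P02662	Tcell	88	111	PNSVEQKHIQKEDVPSERYLGYLE	curated
P02662	Tcell	106	129		curated
P02662	IgE	54	63	ELSKDIGSES	curated
P02662	IgE	64	78	TEDQAMEDIKQMEAE	curated
P02662	IgE	84	93	EEIVPNSVEQ	curated
P02662	IgE	124	135	LEIVPNSAEERL	curated
P02662	IgE	188	207	YTDAPSFSDIPNPIGSENSE	curated
P02662	IgE	190	209	DAPSFSDIPNPIGSENSEKT	curated
P02662	IgE	194	213	FSDIPNPIGSENSEKTTMPL	curated
P02663	Tcell	73	84	SEESAEVATEEV	curated
P02663	IgE	16	34	KNTMEHVSSSEESIISQETY	curated
P02663	IgE	28	47		curated
P02663	IgE	57	71	EVVRNANEEEYSIGS	curated
P02663	IgE	82	101	EEVKITVDDKHYQKALNEIN	curated
P02663	IgE	132	143	VPITPTLNREQL	curated
P02666	IgE	16	31	RELEELNVPGEIVESL	curated
P02666	IgE	31	50	LSSSEESITRINKKIEKFQS	curated
P02666	IgE	49	65	QSEEQQQTEDELQDKIH	curated
P02666	IgE	70	85	TQSLVYPFPGPIPNSL	curated
P02666	IgE	98	107	VVPPFLQPEV	curated
P02668	IgE	132	147	KKNQDKTEIPTINTIA	curated
P02668	IgE	158	169	EAVESTVATLED	curated
P02668	IgE	170	189	SPEVIESPPEINTVQVTSTA	curated
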
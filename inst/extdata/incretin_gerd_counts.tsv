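analysis	target	event	n11	n1plus	nplus1	N
class	GLP-1-RAs (ALL)	GERD-like symptoms	36	429	654	38887
drug	dulaglutide	GERD-like symptoms	1	20	654	38887
drug	exenatide	GERD-like symptoms	19	122	654	38887
drug	liraglutide	GERD-like symptoms	15	278	654	38887
drug	lixisenatide	GERD-like symptoms	1	12	654	38887
class	DPP-4-Is (ALL)	GERD-like symptoms	31	3276	654	38887
drug	alogliptin	GERD-like symptoms	1	345	654	38887
drug	anagliptin	GERD-like symptoms	0	72	654	38887
drug	linagliptin	GERD-like symptoms	4	332	654	38887
drug	omarigliptin	GERD-like symptoms	0	2	654	38887
drug	saxagliptin	GERD-like symptoms	0	70	654	38887
drug	sitagliptin	GERD-like symptoms	16	1181	654	38887
drug	teneligliptin	GERD-like symptoms	0	98	654	38887
drug	trelagliptin	GERD-like symptoms	1	19	654	38887
drug	vildagliptin	GERD-like symptoms	9	1189	654	38887
pt	GLP-1-RAs (ALL)	Vomiting	23	429	344	38887
pt	GLP-1-RAs (ALL)	Nausea	17	429	310	38887
pt	GLP-1-RAs (ALL)	Impaired gastric emptying	1	429	3	38887
pt	GLP-1-RAs (ALL)	Oesophageal ulcer	1	429	18	38887
pt	GLP-1-RAs (ALL)	Gastrooesophageal reflux disease	1	429	24	38887
pt	GLP-1-RAs (ALL)	Dysphagia	1	429	28	38887
pt	GLP-1-RAs (ALL)	Abdominal distension	1	429	33	38887
pt	GLP-1-RAs (ALL)	Erosive oesophagitis	0	429	25	38887
pt	GLP-1-RAs (ALL)	Dyspepsia	0	429	45	38887
pt	DPP-4-Is (ALL)	Vomiting	12	3276	344	38887
pt	DPP-4-Is (ALL)	Nausea	9	3276	310	38887
pt	DPP-4-Is (ALL)	Impaired gastric emptying	0	3276	3	38887
pt	DPP-4-Is (ALL)	Oesophageal ulcer	0	3276	18	38887
pt	DPP-4-Is (ALL)	Gastrooesophageal reflux disease	6	3276	24	38887
pt	DPP-4-Is (ALL)	Dysphagia	5	3276	28	38887
pt	DPP-4-Is (ALL)	Abdominal distension	1	3276	33	38887
pt	DPP-4-Is (ALL)	Erosive oesophagitis	1	3276	25	38887
pt	DPP-4-Is (ALL)	Dyspepsia	1	3276	45	38887
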
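class	drug
GLP-1-RAs	dulaglutide
GLP-1-RAs	exenatide
GLP-1-RAs	liraglutide
GLP-1-RAs	lixisenatide
DPP-4-Is	alogliptin
DPP-4-Is	anagliptin
DPP-4-Is	linagliptin
DPP-4-Is	omarigliptin
DPP-4-Is	saxagliptin
DPP-4-Is	sitagliptin
DPP-4-Is	teneligliptin
DPP-4-Is	trelagliptin
DPP-4-Is	vildagliptin
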
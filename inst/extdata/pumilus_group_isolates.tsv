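isolate	accession	id_16s	pct_identity	id_maldi	log_score
PF9-10.2.1	KT920027.1	B. safensis	100	Bacillus safensis_FO36b^T	2.3
PF9-10.1.1	KT720019.1	B. safensis	100	Bacillus safensis_FO36b^T	2.22
MER_TA_110.2	KT719518.1	B. safensis	99.4	Bacillus safensis_FO36b^T	2.32
AMY_31.2	KT719925.1	B. pumilus	99.2	Bacillus pumilus_DSM 27^T	2.33
AMY_17.1	KT719907.1	B. pumilus	99.8	Bacillus australimaris_LMG_27697^T	2.32
MER_178	KT719762.1	B. australimaris	99.8	Bacillus safensis_FO36b^T	2.24
MER_114.2	KT719690.1	B. zhangzhouensis	99.3	Bacillus pumilus_DSM 27^T	2.36
MSL_3001	KT719852.1	B. pumilus	99.8	Bacillus australimaris_LMG_27697^T	2.19
IN_293	MG881821	B. australimaris	99.8	Bacillus safensis_FO36b^T	2.17
V45.5	KT720340.1	B. pumilus	99.8	Bacillus pumilus_DSM 27^T	2.03
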
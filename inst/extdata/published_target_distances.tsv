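gene	d_essential	d_drug	degree
SULT1E1	1.4744	5.1837	17
WEE1	1.3499	3.1641	47
RGS7	1.3440	3.0462	20
SMN2	1.6241	5.8903	28
RNGTT	1.7738	4.2353	100
STK16	1.6785	3.9232	34
PAK7	1.7091	3.8467	30
NEK2	1.7952	3.5328	47
YWHAG	1.8603	3.3451	339
MAPK10	1.6685	3.0371	27
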
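gene	symbol	sourceTable	log2FoldChange	m0	tau
FBgn0052581	CG32581	bulkSoma	10.012	0.3052	0.7378
FBgn0051157	CG31157	bulkSoma	9.389	0.2962	0.9010
FBgn0039108	CG10232	bulkSoma	7.526	0.7202	0.9260
FBgn0039598	aqrs	bulkSoma	7.217	0.2305	0.9946
FBgn0260479	CG31904	bulkSoma	5.373	0.3038	0.9466
FBgn0044048	Ilp5	bulkSoma	5.343	0.3776	0.8485
FBgn0031900	CG13786	bulkSoma	5.308	0.2487	0.9483
FBgn0050281	CG30281	bulkSoma	5.216	0.2155	0.9820
FBgn0031646	snsl	bulkSoma	5.146	0.2672	0.9408
FBgn0051815	CG31815	bulkSoma	5.070	0.3745	0.9519
FBgn0015872	Drip	overlap	7.798	0.2734	0.9786
FBgn0040343	CG3713	overlap	5.951	0.2636	0.9146
FBgn0002868	MtnA	overlap	4.380	0.6883	0.8753
FBgn0016075	vkg	overlap	4.200	0.3860	0.9037
FBgn0000299	Col4a1	overlap	3.875	0.4065	0.8887
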
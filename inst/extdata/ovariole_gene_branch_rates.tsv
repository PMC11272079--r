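gene	symbol	sourceTable	Dsim	Dsec	Dmel	Dyak	Dere
FBgn0011274	Dif	signaling	0.0001	0.5981	0.0001	0.7233	0.4146
FBgn0014020	Rho1	signaling	-	0.0001	-	0.0001	-
FBgn0003612	Su(var)2-10	signaling	0.5723	0.0001	0.5482	0.0662	0.0122
FBgn0026379	Pten	signaling	0.0001	0.1773	0.3122	0.1278	0.5944
FBgn0000259	CkIIbeta	signaling	0.6516	0.2694	0.0001	0.0001	0.0001
FBgn0035213	CG2199	signaling	1.0905	0.404	0.3582	0.328	0.2765
FBgn0011642	Zyx	signaling	0.3100	>1	0.2877	0.2668	0.3222
FBgn0262614	pyd	signaling	0.0165	0.0341	0.4745	0.0168	0.0969
FBgn0036974	eRF1	signaling	0.0001	0.1445	0.3901	0.0001	0.0697
FBgn0003984	vn	signaling	0.4712	0.2069	0.0841	0.2802	0.1511
FBgn0004858	elB	signaling	0.0001	0.6159	0.0297	0.066	0.0617
FBgn0010825	Gug	signaling	0.5467	0.3674	0.0539	0.0469	0.0416
FBgn0002174	CG5504	signaling	0.2527	0.3135	0.0423	0.0812	0.0937
FBgn0037218	aux	signaling	0.0648	0.1874	0.1639	0.2738	0.2413
FBgn0259176	bun	signaling	0.0661	0.2569	0.1009	0.1814	0.2716
FBgn0023540	CG3630	signaling	0.3585	0.5938	0.1247	0.239	0.1129
FBgn0261854	aPKC	signaling	0.1931	0.0126	0.0001	0.0001	0.0855
FBgn0001169	H	signaling	0.1982	0.1646	0.1585	0.2220	0.1746
FBgn0024291	Sirt1	signaling	0.0001	0.1876	0.2589	0.1113	0.071
FBgn0030904	upd2	signaling	-	0.4168	0.0347	0.0793	0.1667
FBgn0020496	CtBP	signaling	0.5440	0.0001	0.0697	0.0001	0.1103
FBgn0003607	Su(var)205	signaling	0.1102	0.0001	0.2107	0.058	0.0634
FBgn0261592	RpS6	signaling	0.0001	0.3052	0.0179	0.0001	0.0001
FBgn0020386	Pdk1	signaling	0.3558	0.4589	0.0996	0.0624	0.0490
FBgn0002592	E(spl)m2-BFM	signaling	0.5554	0.2217	0.0197	0.1984	0.1469
FBgn0032006	Pvr	signaling	0.0077	0.2500	0.0535	0.1614	0.2063
FBgn0045035	tefu	signaling	0.0868	0.1908	0.1222	0.1051	0.1411
FBgn0052581	CG32581	bulkSoma	0.1647	0.6899	0.5668	0.2455	0.1672
FBgn0051157	CG31157	bulkSoma	0.1163	1.3228	0.1967	0.3405	0.1777
FBgn0039108	CG10232	bulkSoma	>1	2.0881	0.4894	0.6514	0.5914
FBgn0039598	aqrs	bulkSoma	0.1183	0.1097	0.1265	0.3029	0.1972
FBgn0260479	CG31904	bulkSoma	0.0001	0.4808	0.6401	0.0556	0.1363
FBgn0044048	Ilp5	bulkSoma	0.2932	0.5843	0.0001	0.4907	0.5501
FBgn0031900	CG13786	bulkSoma	0.1709	0.2778	0.2748	0.2362	0.3271
FBgn0050281	CG30281	bulkSoma	0.4796	0.613	0.1951	0.1806	0.249
FBgn0031646	snsl	bulkSoma	0.1571	0.0635	0.1566	0.2317	0.585
FBgn0051815	CG31815	bulkSoma	0.1725	0.3185	0.3421	0.4465	0.3695
FBgn0015872	Drip	overlap	0.6248	>1	0.4140	0.3750	0.1312
FBgn0040343	CG3713	overlap	>1	0.0001	0.8226	0.1501	0.3225
FBgn0002868	MtnA	overlap	-	>1	>1	>1	0.1265
FBgn0016075	vkg	overlap	0.3038	0.7557	0.2965	0.3510	0.5572
FBgn0000299	Col4a1	overlap	0.3034	1.2519	0.2072	0.4728	0.6879
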
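dataset	RP-CNN	ResNet	FCN	RP-FCN	HIVE-COTE	FCN-RCF	ALSTM-FCN	MS-RP-ResNet	MS-RP-FCN
Adiac(64,2,1)	0.28	0.174	0.143	0.1709	0.1846	0.155	0.133	0.156	0.1379
Beef(64,2,1)	0.08	0.233	0.25	0.1667	0.2773	0.03	0.0667	0.0667	0.1333
CBF(64,2,1)	0.005	0.006	0	0.0033	6e-04	0	0	0	0
ChlorineCon(112,2,1)	0.1049	0.172	0.157	0.1992	0.2749	0.068	0.193	0.1987	0.1992
CinTorso(128,3,4)	0.0087	0.229	0.187	0.2866	0.012	0.014	0.0942	0.0486	0.1123
Coffee(64,2,1)	0	0	0	0	0.0018	0	0	0	0
CricketX(64,3,4)	0.2718	0.179	0.185	0.2187	0.1696	0.216	0.1949	0.1538	0.1821
CricketY(64,3,4)	0.2462	0.195	0.208	0.2349	0.163	0.172	0.1795	0.1564	0.1718
CricketZ(64,3,4)	0.2667	0.187	0.187	0.2064	0.1523	0.162	0.1692	0.1487	0.1615
DiatomSizeR(64,2,1)	0.0098	0.069	0.07	0.0196	0.0581	0.023	0.0261	0.0065	0.0098
ECG200(64,2,1)	0	0.13	0.1	0.08	0.1181	0.0625	0.09	0.05	0.08
ECGFiveDays(64,3,4)	0.0023	0.045	0.015	0	0.0105	0.01	0.0046	0	0
FaceAll(96,2,1)	0.19	0.166	0.071	0.1775	0.0037	0.098	0.0343	0.0627	0.032
FaceFour(96,2,1)	0	0.068	0.068	0.0341	0.0505	0.05	0.0568	0.0795	0.04
FacesUCR(64,2,1)	0.0483	0.042	0.052	0.0751	0.0164	0.087	0.0566	0.0585	0.0561
FiftyWords(48,3,4)	0.26	0.273	0.321	0.1846	0.1932	0.288	0.1758	0.1692	0.178
Fish(64,2,1)	0.085	0.011	0.029	0	0.0238	0.021	0.0229	0.0114	0
GunPoint(64,2,1)	0	0.007	0	0	0.0033	0	0	0	0
Haptics(64,2,1)	0.539	0.494	0.449	0.4578	0.4697	0.461	0.4351	0.4708	0.4675
InlineSkate(128,2,1)	0.6436	0.635	0.589	0.5382	0.4741	0.566	0.5073	0.5655	0.5491
ItaPowDemand(16,2,1)	0.033	0.04	0.03	0.0447	0.0322	0.031	0.0398	0.0262	0.0292
Lightning2(64,3,4)	0.1639	0.246	0.197	0.0984	0.203	0.145	0.2131	0.1148	0.0984
Lightning7(64,3,4)	0.26	0.164	0.137	0.147	0.1889	0.091	0.1781	0.144	0.1233
Mallat(128,3,4)	0.0512	0.021	0.02	0.0752	0.0245	0.044	0.0162	0.0473	0.0422
MedicalImg(96,2,1)	0.2658	0.228	0.208	0.2329	0.1846	0.164	0.2039	0.2066	0.1947
MoteStrain(80,2,1)	0.1182	0.105	0.05	0.1741	0.0532	0.076	0.0639	0.0847	0.0831
NonInThorax1(128,3,4)	0.058	0.052	0.039	0.058	0.0683	0.026	0.0249	0.0575	0.0361
NonInThorax2(128,3,4)	0.0489	0.049	0.045	0.0579	0.0477	0.028	0.0336	0.0453	0.0366
OliveOil(96,2,1)	0.11	0.133	0.167	0.1333	0.1023	0	0.0667	0.0667	0.05
OSULeaf(96,2,1)	0.29	0.021	0.012	0.0909	0.0295	0.018	0.0041	0.0248	0.0165
SonyAIRobot1(64,2,1)	0.0499	0.015	0.032	0.0266	0.1132	0.042	0.03	0.0166	0.0067
SonyAIRobot2(64,2,1)	0.0923	0.038	0.038	0.0546	0.0546	0.064	0.0252	0.0535	0.021
StarLigCurves(128,3,4)	0.0234	0.025	0.033	0.0238	0.0185	0.018	0.0233	0.0195	0.018
SwedishLeaf(64,2,1)	0.06	0.042	0.034	0.0304	0.0314	0.057	0.0144	0.0272	0.0272
Symbols(64,3,4)	0.0824	0.128	0.038	0.0181	0.0342	0.04	0.0131	0.0141	0.0161
SynControl(64,2,1)	0.3433	0	0.01	0.31	4e-04	0.0382	0.01	0	0
Trace(64,2,1)	0	0	0	0	0	0.094	0	0	0
TwoLeadECG(64,2,1)	0.0026	0	0	0.0018	0.0065	0.0643	9e-04	0	0
TwoPatterns(64,2,1)	0.4935	0	0.103	0.4888	1e-04	0	0.0032	0	0
UWaveX(64,3,4)	0.3582	0.213	0.246	0.3778	0.1616	0.218	0.1519	0.179	0.1963
UWaveY(64,3,4)	0.3439	0.332	0.275	0.3425	0.2245	0.232	0.2342	0.2496	0.2725
UWaveZ(64,2,1)	0.3317	0.245	0.271	0.349	0.2217	0.265	0.2018	0.2272	0.2462
Wafer(64,2,1)	0	0.003	0.003	0.0015	3e-04	0	0.0019	6e-04	0.0011
WoSynonyms(64,2,1)	0.3135	0.368	0.42	0.29	0.252	0.338	0.3323	0.2774	0.2978
Yoga(64,2,1)	0.118	0.142	0.155	0.0953	0.083	0.112	0.081	0.0887	0.093
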
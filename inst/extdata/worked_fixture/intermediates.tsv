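cell	auc	pc	error	cluster
cl0001	15.4870191055	0.0101883340323	0.395781118025	3
cl0002	16.8024307634	1.25452738329	1.73277797163	3
cl0003	8.24235603492	-2.72843386153	-1.58315963423	1
cl0004	11.1407015244	4.49587697128	-0.19617596834	2
cl0005	11.8448663229	4.36869453897	0.505727764315	2
cl0006	17.4802867458	0.00712399675207	3.41108555801	3
cl0007	14.4485664916	-2.12037219595	1.33790821453	3
cl0008	6.89777881385	-4.70208874515	-2.68150002938	1
cl0009	11.7557674684	4.92182421178	0.111217262055	2
cl0010	6.95928459529	-4.97486131964	-2.13179398315	1
cl0011	4.61863896211	-5.80466120542	-4.24712673022	1
cl0012	11.4339952893	-0.757650537231	0.946863400977	2
cl0013	10.0302666419	-2.09117074102	0.094325804283	2
cl0014	7.93462203357	-4.74906021105	-0.913453214523	1
cl0015	13.892147459	2.08091258698	2.63520434327	3
cl0016	11.194318355	4.12538657842	-0.648019067094	2
cl0017	15.1810430426	-1.6219383901	0.465147639534	3
cl0018	11.7378933968	5.99433816706	-0.370182748691	2
cl0019	17.6807269059	-0.185962369833	2.28744933473	3
cl0020	16.857487275	-0.231568741788	2.39155323613	3
cl0021	11.3875370556	5.34725693162	-0.0929317723666	2
cl0022	11.114288526	5.13286539923	-0.322674090641	2
cl0023	17.4224859773	-0.642921723015	2.89218272986	3
cl0024	7.75775248617	-4.92892400168	-1.29447372888	1
cl0025	11.7018186972	6.28091492426	-0.259972447779	2
cl0026	11.1523740639	4.2699845931	-0.704175178704	2
cl0027	14.7744549333	-0.546452558274	0.369820700689	3
cl0028	8.94448457508	-1.9813154265	-1.03284605565	1
cl0029	14.8152699601	-1.37304475402	0.0277836403094	3
cl0030	14.9435860407	-0.374460088665	0.56883223749	3
cl0031	10.734663978	3.84549866959	-0.462138330925	2
cl0032	13.2168284306	5.01574583689	1.22664674887	2
cl0033	11.7115595346	2.02703788617	0.712451398368	2
cl0034	17.0975192564	0.761235369747	2.34920518678	3
cl0035	10.8741549911	3.39795518753	-0.106217968503	2
cl0036	9.18753314454	-2.35470458244	-0.355315992381	2
cl0037	17.2604054914	0.36769396066	2.91909216884	3
cl0038	5.21890402665	-6.62915986262	-3.50943612069	1
cl0039	11.8979598191	4.08016210307	0.370259172692	2
cl0040	10.8677326015	3.94423887035	-0.647124866035	2
cl0041	15.6520787921	-0.339480547357	1.36126104021	3
cl0042	16.8839129797	1.37896772465	2.43094227202	3
cl0043	10.1967855234	-1.26361293393	-0.524010013784	2
cl0044	15.0033061177	-0.504783230988	-0.406677233763	3
cl0045	7.39478201311	-4.22991478398	-1.67775805363	1
cl0046	11.0086599545	4.0901457832	-0.192851906425	2
cl0047	11.4955184782	4.00844183255	-0.0633508826553	2
cl0048	7.78681000267	-4.01138178842	-1.68554040955	1
cl0049	11.0974509997	3.89050327247	-0.513516242995	2
cl0050	6.08738093572	-6.03101203621	-2.9717100374	1
cl0051	7.37871681166	-4.65469438054	-1.95416572517	1
cl0052	14.9511967624	-0.729403292335	0.29363997037	3
cl0053	16.3218087772	1.46098584666	1.00752721118	3
cl0054	7.58225490558	-3.51517845689	-1.83280781865	1
cl0055	8.57408051441	-4.12130096804	-1.16874315707	1
cl0056	7.04152844712	-4.70486974846	-2.60707197994	1
cl0057	14.1562411224	-1.24639549268	-0.34575843464	3
cl0058	15.2995889022	-0.753872038311	0.151833558723	3
cl0059	9.09018554387	-4.51275273074	-0.36989698207	2
cl0060	13.0609952381	2.85889678452	1.68383842246	2
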
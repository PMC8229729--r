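cell	regime	response_true
cl0001	3	15.2997404378441129
cl0002	3	17.0754435034492502
cl0003	1	 8.1194327846569720
cl0004	2	11.0001110963950772
cl0005	2	11.0922544329314530
cl0006	3	17.3119481185941986
cl0007	3	14.6922951416033172
cl0008	1	 7.3293365641793535
cl0009	2	11.7203028792218600
cl0010	1	 7.1660817602931735
cl0011	1	 4.9357785373870628
cl0012	1	11.5430843744409177
cl0013	1	 9.6590331621550902
cl0014	1	 8.2064303209882699
cl0015	2	13.7745450486582151
cl0016	2	11.0225867299790519
cl0017	3	15.1665875595115125
cl0018	2	11.6946737635204610
cl0019	3	17.4982762351887331
cl0020	3	16.9607296087809623
cl0021	2	11.2921459259794119
cl0022	2	11.2481380267221667
cl0023	3	17.0815239632877400
cl0024	1	 7.6273704675262799
cl0025	2	12.1095249871851944
cl0026	2	11.0002505783217064
cl0027	3	14.9362022064206688
cl0028	1	 9.1760406684174836
cl0029	3	14.5107757807679523
cl0030	3	14.8357736677377634
cl0031	2	11.3841941372130933
cl0032	2	12.3257693699866984
cl0033	2	11.9987385585111888
cl0034	3	17.2477241449702667
cl0035	2	11.1975502601386641
cl0036	1	 9.0501657055415130
cl0037	3	17.3853573433442499
cl0038	1	 5.2449603038293198
cl0039	2	11.9898827357178615
cl0040	2	11.0210691142758268
cl0041	3	15.8268615667598311
cl0042	3	16.7831607296047345
cl0043	1	10.4495874417834358
cl0044	3	15.3234191808842475
cl0045	1	 7.4892439505262827
cl0046	2	11.0008515720140405
cl0047	2	11.1285635502975886
cl0048	1	 7.8984294744414463
cl0049	2	11.0436585810970485
cl0050	1	 5.8402096496619187
cl0051	1	 7.1928862520540351
cl0052	3	14.5623035280838611
cl0053	3	16.7090808167564759
cl0054	1	 7.4210648305745917
cl0055	1	 8.5049430904764893
cl0056	1	 7.6498479354691780
cl0057	3	14.5375924654022910
cl0058	3	15.4987503437620724
cl0059	1	 8.8890913450641236
cl0060	2	12.8493175248114984
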
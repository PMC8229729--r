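drug_id	cl0001	cl0002	cl0003	cl0004	cl0005	cl0006	cl0007	cl0008	cl0009	cl0010	cl0011	cl0012	cl0013	cl0014	cl0015	cl0016	cl0017	cl0018	cl0019	cl0020	cl0021	cl0022	cl0023	cl0024	cl0025	cl0026	cl0027	cl0028	cl0029	cl0030	cl0031	cl0032	cl0033	cl0034	cl0035	cl0036	cl0037	cl0038	cl0039	cl0040	cl0041	cl0042	cl0043	cl0044	cl0045	cl0046	cl0047	cl0048	cl0049	cl0050	cl0051	cl0052	cl0053	cl0054	cl0055	cl0056	cl0057	cl0058	cl0059	cl0060
synthetic_drug	15.487019105472209	16.802430763441368	8.2423560349200873	11.140701524368859	11.844866322906247	17.480286745823413	14.448566491641776	6.8977788138493494	11.755767468369992	6.9592845952867624	4.6186389621104995	11.433995289278116	10.030266641859656	7.9346220335659794	13.892147459011813	11.194318355001064	15.181043042613743	11.7378933968266	17.680726905933493	16.857487275002111	11.387537055595317	11.114288526025494	17.4224859773012	7.7577524861667619	11.701818697171403	11.152374063900199	14.774454933258742	8.9444845750767232	14.815269960139496	14.943586040728723	10.734663978046699	13.216828430618252	11.711559534550261	17.097519256381311	10.874154991059994	9.187533144537829	17.260405491406129	5.2189040266519786	11.897959819126669	10.867732601512266	15.652078792098926	16.883912979696518	10.196785523368835	15.003306117714073	7.3947820131094817	11.008659954461447	11.495518478224515	7.7868100026731168	11.097450999734573	6.0873809357241901	7.3787168116637298	14.951196762416695	16.321808777178134	7.5822549055754846	8.5740805144091983	7.0415284471228023	14.1562411224455	15.299588902210276	9.0901855438742896	13.060995238131133
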
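metabolite	mode	psi	pp_DDE	pp_DDT	HCB	PCB118	PCB153	PBDE47
palmitoleate	C18-	-0.682	-0.238	0.013	-0.241	0.150	-0.309	-0.056
stearidonic acid	C18-	-0.873	-0.163	-0.075	-0.185	0.019	-0.274	-0.194
11-octadecen-9-ynoic acid	C18-	-0.713	-0.355	0.208	-0.325	-0.038	-0.197	-0.007
arachidonic acid	C18-	-0.793	-0.208	-0.108	-0.233	0.077	-0.146	-0.174
histidine	C18-	-0.689	-0.464	0.309	-0.307	-0.195	0.081	-0.113
acetoacetate	HILIC-	-0.779	-0.319	-0.029	-0.229	-0.048	0.011	-0.164
3-hydroxyanthranilate	HILIC-	-0.663	-0.073	-0.123	-0.234	0.005	-0.162	-0.076
asparagine	HILIC+	-0.671	-0.252	-0.148	-0.191	0.272	-0.281	-0.071
indole-3-acetate	HILIC+	-0.729	-0.150	-0.192	-0.210	0.156	-0.204	-0.130
hypoxanthine	HILIC+	-0.699	-0.034	-0.124	-0.186	-0.010	-0.094	-0.252
inosine	HILIC+	-0.700	-0.162	-0.270	-0.216	0.004	-0.022	-0.033
N,N-dimethylarginine	HILIC+	-0.614	-0.217	-0.093	-0.109	0.022	-0.237	0.021
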
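kinase	element	start	end
CDK1	n_lobe	1	80
CDK1	c_lobe	85	297
CDK1	hinge	81	84
CDK1	p_loop	11	17
CDK1	c_helix	46	57
CDK1	activation_segment	146	173
CDK1	beta_sheet_base	8	10
CDK1	beta_sheet_base	17	19
CDK1	beta_sheet_base	29	31
CDK1	beta_sheet_base	63	65
CDK1	beta_sheet_base	78	80
CDK1	r_spine	55	55
CDK1	r_spine	66	66
CDK1	r_spine	126	126
CDK1	r_spine	147	147
CDK1	c_spine	18	18
CDK1	c_spine	31	31
CDK1	c_spine	64	64
CDK1	c_spine	80	80
CDK1	c_spine	134	134
CDK1	c_spine	135	135
CDK1	c_spine	136	136
CDK1	gatekeeper	80	80
CDK1	ploop_tyrosine	15	15
CDK1	activation_glutamate	163	163
CDK2	n_lobe	1	80
CDK2	c_lobe	85	298
CDK2	hinge	81	84
CDK2	p_loop	11	17
CDK2	c_helix	46	57
CDK2	activation_segment	145	172
CDK2	beta_sheet_base	8	10
CDK2	beta_sheet_base	17	19
CDK2	beta_sheet_base	29	31
CDK2	beta_sheet_base	63	65
CDK2	beta_sheet_base	78	80
CDK2	r_spine	55	55
CDK2	r_spine	66	66
CDK2	r_spine	125	125
CDK2	r_spine	146	146
CDK2	c_spine	18	18
CDK2	c_spine	31	31
CDK2	c_spine	64	64
CDK2	c_spine	80	80
CDK2	c_spine	133	133
CDK2	c_spine	134	134
CDK2	c_spine	135	135
CDK2	gatekeeper	80	80
CDK2	ploop_tyrosine	15	15
CDK2	activation_glutamate	162	162
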